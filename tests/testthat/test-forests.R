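test_that("within-sample permutation preserves each row's value multiset", {
  set.seed(10)
  m <- matrix(runif(6 * 20), 6, 20,
              dimnames = list(sprintf("s%d", 1:6), sprintf("N%d", 21:40)))
  p <- permute_within_samples(m, seed = 1)
  for (i in 1:6) expect_equal(sort(unname(p[i, ])), sort(unname(m[i, ])))
  expect_equal(rowSums(p), rowSums(m))
  expect_identical(p, permute_within_samples(m, seed = 1))  # determinism
  expect_false(identical(p, m))
  expect_identical(dimnames(p), dimnames(m))
  expect_error(permute_within_samples(m[, 1, drop = FALSE]), ">= 2 features")
})

test_that("forest fitting is deterministic, controlled and validated", {
  ds <- planted_dataset(n_tips = 80)
  cfg <- forest_config("niche", c("age", "genotype"), n_trees = 300, seed = 5)
  r1 <- fit_criterion_forest(ds$cm, ds$metadata, cfg)
  r2 <- fit_criterion_forest(ds$cm, ds$metadata, cfg)
  expect_identical(r1$oob_accuracy, r2$oob_accuracy)
  expect_identical(r1$mda, r2$mda)

  # covariate indicators present, clades flagged
  expect_true(any(grepl("^cov_age_", r1$feature_ids)))
  expect_equal(sum(r1$is_clade), ncol(ds$cm))
  expect_equal(length(r1$mda), length(r1$feature_ids))  # MDA covers all
  # default mtry = floor(sqrt(#features))
  expect_equal(r1$mtry, floor(sqrt(length(r1$feature_ids))))

  expect_error(forest_config("niche", c("niche", "age")), "exclude")
  md1 <- ds$metadata; md1$niche <- "stool"
  expect_error(fit_criterion_forest(ds$cm, md1, cfg), "single level")
  md2 <- ds$metadata; md2$age[3] <- NA
  expect_error(fit_criterion_forest(ds$cm, md2, cfg),
               rownames(md2)[3])
})

test_that("label-independent forests sit at the majority-class rate", {
  set.seed(20)
  accs <- replicate(15, {
    tr <- simulate_tree(40)
    md <- simulate_design(design_spec())
    md$coin <- sample(rep(c("h", "t"), 20))   # label independent of features
    cnt <- simulate_counts(tr, md, mother_sigma = 0, cage_sigma = 0)
    cm <- clade_abundance_matrix(tr, cnt)
    fit_criterion_forest(cm, md, forest_config("coin", n_trees = 300))$oob_accuracy
  })
  # within 3 Monte-Carlo SD of the majority-class rate (0.5)
  expect_lt(abs(mean(accs) - 0.5), 3 * sd(accs) / sqrt(length(accs)) + 0.02)
})

test_that("a planted fold-4 clade is recovered near the top of the MDA ranking", {
  ds <- planted_dataset(n_tips = 150, fold = 4)
  cfg <- forest_config("niche", c("age", "genotype"), n_trees = 1000, seed = 3)
  res <- fit_criterion_forest(ds$cm, ds$metadata, cfg)
  planted <- ds$effects$clade_id[ds$effects$factor == "niche"]
  ranks <- vapply(planted, function(nd) cladeforest:::clade_mda_rank(res, nd),
                  numeric(1))
  # top 1% of ~149 clades is rank 1-2; accept the planted set reaching it
  expect_lte(min(ranks), max(2, ceiling(0.01 * sum(res$is_clade))))
  top <- top_important_clades(res, k = 5, tree = ds$tree)
  expect_true(any(top$clade_id %in% planted))
})

test_that("null forest keeps covariates and centres MDA near zero", {
  ds <- planted_dataset(n_tips = 80)
  cfg <- forest_config("niche", c("age", "genotype"), n_trees = 500, seed = 9)
  nf <- null_forest(ds$cm, ds$metadata, cfg)
  expect_equal(sum(nf$is_clade), ncol(ds$cm))
  mda <- nf$mda[nf$is_clade]
  expect_lt(abs(mean(mda)), 3 * sd(mda) / sqrt(length(mda)) + 1e-4)
  # planted real signal beats the null clearly
  rf <- fit_criterion_forest(ds$cm, ds$metadata, cfg)
  expect_gt(rf$oob_accuracy, nf$oob_accuracy + 0.2)
})

test_that("top_important_clades orders by MDA with deterministic ties", {
  ds <- planted_dataset(n_tips = 60)
  cfg <- forest_config("niche", n_trees = 100, seed = 1)
  res <- fit_criterion_forest(ds$cm, ds$metadata, cfg)
  top <- top_important_clades(res, k = 5)
  expect_equal(nrow(top), 5)
  expect_true(all(diff(top$mda) <= 0))
  # all-equal MDA -> ordering by clade id
  res2 <- res
  res2$mda[] <- 1
  t2 <- top_important_clades(res2, k = 3)
  expect_equal(t2$clade_id,
               sort(res$feature_ids[res$is_clade])[1:3])
  expect_warning(top_important_clades(res, k = 10 + sum(res$is_clade)),
                 "truncating")
})

test_that("real-vs-null comparison uses two-way ANOVA with Sidak contrasts", {
  # identical accuracy vectors in both arms -> contrast p = 1
  same <- data.frame(criterion = rep(c("a", "b"), each = 3),
                     accuracy = rep(c(0.6, 0.7, 0.8), 2))
  cmp <- compare_real_null_accuracy(same, same)
  expect_equal(cmp$p, c(1, 1))

  # m = 1 criterion: Sidak leaves p unchanged
  one <- data.frame(criterion = "a", accuracy = c(0.9, 0.92, 0.91))
  onen <- data.frame(criterion = "a", accuracy = c(0.5, 0.52, 0.51))
  c1 <- compare_real_null_accuracy(one, onen)
  expect_equal(c1$p_sidak, c1$p)

  # strong separation over 6 replicates -> adjusted p < 1e-4
  set.seed(30)
  real <- data.frame(criterion = rep(c("niche", "age"), each = 6),
                     accuracy = 0.95 + rnorm(12, 0, 0.01))
  null <- data.frame(criterion = rep(c("niche", "age"), each = 6),
                     accuracy = 0.50 + rnorm(12, 0, 0.01))
  c2 <- compare_real_null_accuracy(real, null)
  expect_true(all(c2$p_sidak < 1e-4))

  expect_error(compare_real_null_accuracy(
    real, null[1:8, ]), "unbalanced|empty")
})
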