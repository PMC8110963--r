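test_that("spike redistribution conserves mass and supports a no-op", {
  set.seed(40)
  m <- matrix(runif(8 * 5), 8, 5,
              dimnames = list(sprintf("s%d", 1:8), sprintf("N%d", 9:13)))
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  sp <- spike_redistribute(m, "N10", mask)
  expect_equal(sum(sp[, "N10"]), sum(m[, "N10"]))   # mass conserved
  expect_true(all(sp[!mask, "N10"] == 0))
  expect_identical(sp[, -2], m[, -2])
  # mask covering all samples redistributes proportionally: a no-op
  expect_equal(spike_redistribute(m, "N10", rep(TRUE, 8)), m)
  # group with no original mass gets a uniform share
  m0 <- m; m0[mask, "N10"] <- 0
  sp0 <- spike_redistribute(m0, "N10", mask)
  expect_equal(unname(sp0[mask, "N10"]), rep(sum(m0[, "N10"]) / 3, 3))
  expect_error(spike_redistribute(m, "Nxx", mask), "unknown clade")
})

test_that("MDA correlation across seeds is reproducible machinery", {
  ds <- planted_dataset(n_tips = 60)
  tab <- forest_size_reproducibility(ds$cm, ds$metadata, "niche",
                                     sizes = c(50, 400), n_seeds = 3,
                                     base_seed = 2)
  expect_equal(tab$size, c(50, 400))
  expect_true(all(tab$mean_spearman >= -1 & tab$mean_spearman <= 1))
  # the same seed repeated gives identical MDA, hence correlation exactly 1
  cfg <- forest_config("niche", n_trees = 100, seed = 4)
  a <- fit_criterion_forest(ds$cm, ds$metadata, cfg)
  b <- fit_criterion_forest(ds$cm, ds$metadata, cfg)
  expect_equal(cor(a$mda, b$mda, method = "spearman"), 1)
  expect_error(forest_size_reproducibility(ds$cm, ds$metadata, "niche",
                                           sizes = c(0, 10)), ">= 1")
})

test_that("Monod fit inverts its own curve and flags degeneracy", {
  n <- c(50, 200, 1000, 5000)
  r <- 0.95 * n / (300 + n)
  fit <- fit_monod(n, r)
  expect_equal(fit$a, 0.95, tolerance = 1e-6)
  expect_equal(fit$b, 300, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  expect_false(fit$boundary)
  expect_equal(fit$fitted(300), 0.95 * 300 / 600, tolerance = 1e-6)

  const <- fit_monod(n, rep(0.8, 4))
  expect_true(const$boundary)          # b at its lower bound
  expect_equal(const$a, 0.8, tolerance = 1e-4)

  expect_error(fit_monod(c(10, 20), c(0.1, 0.2)), ">= 3")
})

test_that("technical replicate swaps give consistent forests", {
  ds <- planted_dataset(n_tips = 60)
  # append three identical technical replicates of the first stool sample
  base <- ds$cm[1, , drop = FALSE]
  reps <- base[rep(1, 3), ]
  rownames(reps) <- sprintf("rep%d", 1:3)
  cm <- rbind(ds$cm[-1, ], reps)
  md <- ds$metadata[c(2:nrow(ds$metadata), 1, 1, 1), ]
  rownames(md) <- c(rownames(ds$metadata)[-1], rownames(reps))
  md$sample_id <- rownames(md)
  md$replicate_of <- c(rep(NA, nrow(ds$metadata) - 1), rep("m01_stool", 3))
  out <- replicate_consistency(cm, md, "niche", n_trees = 200, seed = 6)
  expect_equal(nrow(out$per_replicate), 3)     # one row per replicate
  expect_equal(unname(out$mda_cor[lower.tri(out$mda_cor)]), rep(1, 3))
  expect_equal(length(unique(out$per_replicate$oob_accuracy)), 1)

  md_bad <- md; md_bad$age[md_bad$sample_id == "rep2"] <- "18wk"
  md_bad$age[md_bad$sample_id == "rep1"] <- "6wk"
  expect_error(replicate_consistency(cm, md_bad, "niche", n_trees = 50),
               "disagree")
  expect_error(replicate_consistency(ds$cm, ds$metadata, "niche"),
               "replicate_of")
})

test_that("redrawn multinomial replicates keep MDA rankings correlated", {
  ds <- planted_dataset(n_tips = 60, fold = 6)
  set.seed(50)
  tot <- 10000
  p1 <- ds$counts[1, ] / sum(ds$counts[1, ])
  reps <- t(replicate(2, {
    cnt <- ds$counts
    cnt[1, ] <- rmultinom(1, tot, p1)[, 1]
    cnt[1, ]
  }))
  cm_reps <- lapply(1:2, function(i) {
    cnt <- ds$counts; cnt[1, ] <- reps[i, ]
    clade_abundance_matrix(ds$tree, cnt)
  })
  cm <- rbind(cm_reps[[1]][1, , drop = FALSE], cm_reps[[2]][1, , drop = FALSE],
              ds$cm[-1, ])
  rownames(cm)[1:2] <- c("rep1", "rep2")
  md <- ds$metadata[c(1, 1, 2:nrow(ds$metadata)), ]
  rownames(md) <- c("rep1", "rep2", rownames(ds$metadata)[-1])
  md$sample_id <- rownames(md)
  md$replicate_of <- c("m01_stool", "m01_stool",
                       rep(NA, nrow(ds$metadata) - 1))
  out <- replicate_consistency(cm, md, "niche", n_trees = 800, seed = 8)
  expect_gt(out$mean_correlation, 0.8)
})

test_that("cross-forest importance correlation compares against a null band", {
  ds <- planted_dataset(n_tips = 60)
  cfg <- forest_config("niche", n_trees = 200, seed = 11)
  a <- fit_criterion_forest(ds$cm, ds$metadata, cfg)
  expect_equal(cross_forest_importance_correlation(a, a)$rho, 1)  # a = b

  b <- fit_criterion_forest(ds$cm, ds$metadata,
                            forest_config("age", n_trees = 200, seed = 12))
  nulls <- lapply(1:4, function(k) list(
    null_forest(ds$cm, ds$metadata,
                forest_config("niche", n_trees = 200, seed = 100 + k)),
    null_forest(ds$cm, ds$metadata,
                forest_config("age", n_trees = 200, seed = 200 + k))))
  out <- cross_forest_importance_correlation(a, b, nulls)
  expect_equal(length(out$null_rho), 4)
  expect_true(all(abs(out$null_rho) < 0.5))

  small <- fit_criterion_forest(ds$cm[, 1:10], ds$metadata,
                                forest_config("niche", n_trees = 50, seed = 1))
  expect_error(cross_forest_importance_correlation(a, small), "different")
})

test_that("scale profiles expose real-null separation structure", {
  ds <- planted_dataset(n_tips = 100)
  ann <- annotate_clades(ds$tree, ds$counts)
  cfg <- forest_config("niche", c("age", "genotype"), n_trees = 500, seed = 13)
  rf <- fit_criterion_forest(ds$cm, ds$metadata, cfg)
  nf <- null_forest(ds$cm, ds$metadata, cfg)
  pr <- importance_scale_profile(rf, nf, ann, axis = "depth",
                                 n_boot = 50, seed = 14)
  expect_equal(nrow(pr$points), ncol(ds$cm))   # every clade exactly once
  expect_false(any(duplicated(pr$points$clade_id)))
  sep <- profile_separation(pr)
  expect_equal(nrow(sep), nrow(pr$grid))
  # reproducible given parameters
  pr2 <- importance_scale_profile(rf, nf, ann, axis = "depth",
                                  n_boot = 50, seed = 14)
  expect_identical(pr$grid, pr2$grid)

  # null-vs-null profile shows no systematic separation
  nf2 <- null_forest(ds$cm, ds$metadata,
                     forest_config("niche", c("age", "genotype"),
                                   n_trees = 500, seed = 15))
  pr0 <- importance_scale_profile(nf, nf2, ann, axis = "depth",
                                  n_boot = 50, seed = 16)
  s0 <- profile_separation(pr0)
  expect_gte(mean(s0$bands_overlap), 0.95)   # band overlap on >= 95% of axis

  expect_error(importance_scale_profile(rf, nf, ann[-1, ], axis = "depth"),
               "missing clade")
  tr_nolen <- ds$tree; tr_nolen$edge.length <- NULL
  ann_nolen <- annotate_clades(tr_nolen, ds$counts)
  expect_error(importance_scale_profile(rf, nf, ann_nolen,
                                        axis = "root_distance"),
               "branch lengths")
})

test_that("spiking an age clade into one genotype promotes it there", {
  ds <- planted_dataset(n_tips = 100, fold = 4, seed = 21)
  out <- spike_redistribution_test(ds$cm, ds$metadata,
                                   source_target = "age",
                                   spike_target = "genotype",
                                   group_level = "WT",
                                   rank_window = 20, n_trees = 600, seed = 22)
  expect_equal(out$mass_after, out$mass_before)
  expect_lte(out$rank_after, 20)
  expect_lt(out$rank_after, out$rank_before)
})
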