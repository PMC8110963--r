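#' Configure a per-criterion random forest
#'
#' @param target metadata column to predict (e.g. \code{"niche"}, \code{"age"},
#'   \code{"genotype"}, \code{"cage"}, \code{"mother"}).
#' @param covariates other treatment columns supplied as indicator-encoded
#'   explanatory variables, so the forest is controlled for them; must not
#'   include the target.
#' @param n_trees forest size. The reference analysis used 100,000 trees; the
#'   desk default is 1,000 (see \code{\link{forest_size_reproducibility}} for
#'   quantifying the cost of fewer trees).
#' @param mtry candidate features per split; default
#'   \code{floor(sqrt(number of features))}.
#' @param seed integer seed; forests are exactly reproducible given the seed.
#' @return a \code{forest_config} list.
#' @export
forest_config <- function(target, covariates = character(), n_trees = 1000,
                          mtry = NULL, seed = NULL) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (target %in% covariates) stop("covariates must exclude the target")
  structure(list(target = target, covariates = covariates,
                 n_trees = as.integer(n_trees), mtry = mtry, seed = seed),
            class = "forest_config")
}

#' Fit a criterion-discriminating random forest
#'
#' Classification forest on the clade relative-abundance features plus
#' indicator-encoded covariates. Out-of-bag (OOB) accuracy (1 - OOB error
#' rate) estimates predictive accuracy; per-feature importance is the raw
#' mean decrease in accuracy (MDA): the average over trees of (that tree's
#' OOB accuracy) minus (its OOB accuracy after permuting the feature among
#' its OOB samples), unscaled.
#'
#' @param features numeric matrix samples x clades (see
#'   \code{\link{clade_abundance_matrix}}).
#' @param metadata data.frame with the target and covariate columns; rows
#'   matched to \code{features} by sample id.
#' @param config a \code{\link{forest_config}}.
#' @return object of class \code{forest_result}: \code{oob_accuracy},
#'   \code{mda} (named, covering every feature), \code{is_clade} flag per
#'   feature, \code{oob_covered} (every sample out-of-bag at least once),
#'   \code{config}, \code{levels}, \code{majority_rate}.
#' @export
fit_criterion_forest <- function(features, metadata, config) {
  stopifnot(inherits(config, "forest_config"))
  features <- as.matrix(features)
  metadata <- align_metadata(features, metadata)
  cols <- c(config$target, config$covariates)
  miss <- setdiff(cols, colnames(metadata))
  if (length(miss)) stop("metadata column(s) missing: ",
                         paste(miss, collapse = ", "))
  bad <- rownames(metadata)[rowSums(is.na(metadata[, cols, drop = FALSE])) > 0]
  if (length(bad)) stop("samples with missing metadata: ",
                        paste(bad, collapse = ", "))
  y <- factor(metadata[[config$target]])
  if (nlevels(y) < 2) stop("target '", config$target,
                           "' has a single level")
  x <- features
  if (length(config$covariates)) {
    ind <- covariate_indicators(metadata, config$covariates)
    x <- cbind(features, ind)
  }
  mtry <- config$mtry %||% max(1L, floor(sqrt(ncol(x))))
  if (!is.null(config$seed)) set.seed(config$seed)
  rf <- randomForest::randomForest(x, y, ntree = config$n_trees,
                                   mtry = mtry, importance = TRUE)
  mda <- rf$importance[, "MeanDecreaseAccuracy"]
  oob_covered <- all(rf$oob.times > 0)
  if (!oob_covered)
    warning("some samples never out-of-bag; oob_accuracy flagged unreliable")
  structure(list(
    config = config,
    oob_accuracy = 1 - rf$err.rate[config$n_trees, "OOB"],
    mda = mda,
    feature_ids = colnames(x),
    is_clade = colnames(x) %in% colnames(features),
    oob_covered = oob_covered,
    levels = levels(y),
    majority_rate = max(table(y)) / length(y),
    confusion = rf$confusion,
    mtry = mtry), class = "forest_result")
}

align_metadata <- function(features, metadata) {
  ids <- rownames(features)
  if (!is.null(ids) && !is.null(rownames(metadata)) &&
      !identical(rownames(metadata), ids)) {
    if (!all(ids %in% rownames(metadata)))
      stop("feature samples missing from metadata: ",
           paste(setdiff(ids, rownames(metadata)), collapse = ", "))
    metadata <- metadata[ids, , drop = FALSE]
  }
  if (nrow(metadata) != nrow(features))
    stop("metadata rows do not match feature rows")
  metadata
}

covariate_indicators <- function(metadata, covariates) {
  blocks <- lapply(covariates, function(v) {
    f <- factor(metadata[[v]])
    m <- stats::model.matrix(~ 0 + f)
    colnames(m) <- sprintf("cov_%s_%s", v, levels(f))
    m
  })
  ind <- do.call(cbind, blocks)
  rownames(ind) <- rownames(metadata)
  ind
}

#' @export
print.forest_result <- function(x, ...) {
  cat(sprintf("Random forest for '%s' (%d trees, mtry %d): OOB accuracy %.3f (majority-class rate %.3f)\n",
              x$config$target, x$config$n_trees, x$mtry, x$oob_accuracy,
              x$majority_rate))
  cat(sprintf("  %d features (%d clades, %d covariate indicators)\n",
              length(x$mda), sum(x$is_clade), sum(!x$is_clade)))
  invisible(x)
}

#' Permute abundances among clades within each sample
#'
#' The negative-control transform: each sample row's multiset of clade
#' abundances is preserved but its assignment to clades is shuffled,
#' independently per row. True clade-label associations are destroyed while
#' per-sample characteristics (e.g. coverage-driven value distributions) are
#' retained. The root column is deliberately no longer fixed at 1.
#'
#' @param features numeric matrix samples x clades.
#' @param seed integer seed.
#' @return matrix of the same shape and dimnames.
#' @export
permute_within_samples <- function(features, seed = NULL) {
  features <- as.matrix(features)
  if (ncol(features) < 2) stop("need >= 2 features to permute")
  if (!is.null(seed)) set.seed(seed)
  out <- features
  for (i in seq_len(nrow(features))) {
    out[i, ] <- features[i, sample.int(ncol(features))]
  }
  out
}

#' Fit the permutation-null control forest
#'
#' Applies \code{\link{permute_within_samples}} to the clade features and
#' refits the same forest. Covariate indicators are design labels, not taxa,
#' so they are not permuted.
#'
#' @inheritParams fit_criterion_forest
#' @param permutation_seed seed for the within-sample shuffle (default:
#'   \code{config$seed}).
#' @return a \code{forest_result}.
#' @export
null_forest <- function(features, metadata, config,
                        permutation_seed = config$seed) {
  fit_criterion_forest(permute_within_samples(features, permutation_seed),
                       metadata, config)
}

#' Top clades by importance
#'
#' Ranks clade features (covariate indicators excluded) by MDA, descending,
#' ties broken by clade id for determinism. With a tree and lineage map the
#' clades are labelled by their finest common taxon and annotated with depth.
#'
#' @param result a \code{forest_result}.
#' @param k number of clades (default 5).
#' @param tree optional rooted \code{phylo} for depth/taxon annotation.
#' @param taxonomy optional lineage map (see
#'   \code{\link{finest_common_taxon}}).
#' @return data.frame: clade_id, mda, rank, and depth / taxon_label when the
#'   tree (and taxonomy) are given.
#' @export
top_important_clades <- function(result, k = 5, tree = NULL, taxonomy = NULL) {
  stopifnot(inherits(result, "forest_result"))
  mda <- result$mda[result$is_clade]
  if (k > length(mda)) {
    warning("k exceeds the number of clade features; truncating to ",
            length(mda))
    k <- length(mda)
  }
  ord <- order(-mda, names(mda))
  top <- ord[seq_len(k)]
  out <- data.frame(clade_id = names(mda)[top], mda = unname(mda[top]),
                    rank = seq_len(k), stringsAsFactors = FALSE)
  if (!is.null(tree)) {
    depth <- node_depths(tree)
    out$depth <- depth[node_num(out$clade_id)]
    if (!is.null(taxonomy))
      out$taxon_label <- vapply(out$clade_id, function(nd)
        finest_common_taxon(tree, nd, taxonomy), character(1))
  }
  out
}

# dense MDA rank of one clade (1 = most important), ties by clade id
clade_mda_rank <- function(result, clade_id) {
  mda <- result$mda[result$is_clade]
  ord <- order(-mda, names(mda))
  match(clade_id, names(mda)[ord])
}

#' Compare real and null forest accuracies
#'
#' Two-way ANOVA of OOB accuracy on criterion x model arm (real/null) over
#' replicate forests, followed by per-criterion real-vs-null contrasts using
#' the pooled residual variance, Sidak-adjusted:
#' \eqn{p_{adj} = 1 - (1 - p)^m} with m the number of criteria.
#'
#' @param real,null either data.frames with columns \code{criterion} and
#'   \code{accuracy} (one row per replicate forest) or lists of
#'   \code{forest_result}s.
#' @return data.frame (class \code{cf_accuracy_comparison}): per criterion
#'   the arm means, SEs, contrast estimate, t, p and Sidak-adjusted p.
#' @export
compare_real_null_accuracy <- function(real, null) {
  real <- accuracy_table(real); null <- accuracy_table(null)
  df <- rbind(cbind(real, arm = "real"), cbind(null, arm = "null"))
  cells <- table(df$criterion, df$arm)
  if (any(cells == 0)) stop("empty criterion x arm cell(s)")
  if (length(unique(as.vector(cells))) != 1)
    stop("unbalanced replicate counts across criterion x arm cells")
  if (any(cells < 2)) stop("need >= 2 replicates per arm")
  df$criterion <- factor(df$criterion); df$arm <- factor(df$arm)
  fit <- if (nlevels(df$criterion) > 1)
    stats::aov(accuracy ~ criterion * arm, data = df)
  else stats::aov(accuracy ~ arm, data = df)
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  m <- nlevels(df$criterion)
  out <- do.call(rbind, lapply(levels(df$criterion), function(cr) {
    a <- df$accuracy[df$criterion == cr & df$arm == "real"]
    b <- df$accuracy[df$criterion == cr & df$arm == "null"]
    diff <- mean(a) - mean(b)
    se <- sqrt(mse * (1 / length(a) + 1 / length(b)))
    t <- if (se == 0) { if (diff == 0) 0 else sign(diff) * Inf } else diff / se
    p <- 2 * stats::pt(-abs(t), fit$df.residual)
    data.frame(criterion = cr, mean_real = mean(a), se_real = stats::sd(a) / sqrt(length(a)),
               mean_null = mean(b), se_null = stats::sd(b) / sqrt(length(b)),
               diff = diff, t = t, df = fit$df.residual, p = p,
               # 1 - (1 - p)^m, kept accurate for very small p
               p_sidak = -expm1(m * log1p(-p)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("cf_accuracy_comparison", "data.frame")
  attr(out, "anova") <- summary(fit)
  out
}

accuracy_table <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("criterion", "accuracy") %in% colnames(x)))
    return(x[, c("criterion", "accuracy")])
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "forest_result"))) {
    return(data.frame(
      criterion = vapply(x, function(r) r$config$target, character(1)),
      accuracy = vapply(x, function(r) r$oob_accuracy, numeric(1)),
      stringsAsFactors = FALSE))
  }
  stop("expected a data.frame(criterion, accuracy) or a list of forest_result")
}
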