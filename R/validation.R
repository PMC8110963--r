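#' Redistribute a clade's abundance to one sample group
#'
#' Moves the entire abundance mass of one clade column onto the samples in
#' \code{mask} (proportionally to their original values, or uniformly if the
#' group carried none), zeroing it elsewhere. Total column mass is conserved.
#' A mask covering every sample is a no-op.
#'
#' @param features numeric matrix samples x clades.
#' @param clade_id column to redistribute.
#' @param mask logical vector (length = samples): receivers of the mass.
#' @return modified feature matrix.
#' @export
spike_redistribute <- function(features, clade_id, mask) {
  features <- as.matrix(features)
  if (!clade_id %in% colnames(features)) stop("unknown clade: ", clade_id)
  if (length(mask) != nrow(features)) stop("mask length mismatch")
  if (!any(mask)) stop("mask selects no samples")
  col <- features[, clade_id]
  mass <- sum(col)
  w <- col[mask]
  w <- if (sum(w) > 0) w / sum(w) else rep(1 / sum(mask), sum(mask))
  new <- numeric(length(col))
  new[mask] <- mass * w
  features[, clade_id] <- new
  features
}

#' Spike redistribution validation test
#'
#' Takes an important clade from a source forest (e.g. the top age clade),
#' redistributes its abundance to only the samples of one level of another
#' factor (e.g. genotype = WT), refits the forest for that factor, and
#' reports whether the spiked clade now ranks among its most important
#' features. A factor with no true community effect should pick the spike up,
#' confirming the forests respond to planted single-clade signal.
#'
#' @param features clade abundance matrix.
#' @param metadata sample metadata.
#' @param source_target factor whose forest nominates the clade.
#' @param spike_target factor whose forest is refitted after the spike.
#' @param group_level level of \code{spike_target} that receives the mass.
#' @param node_id clade to spike (default: the source forest's top clade).
#' @param rank_window report whether the post-spike rank falls within this
#'   window (default 20).
#' @param n_trees,seed forest parameters.
#' @param covariates covariates for both forests; default: the treatment
#'   columns among niche/age/genotype other than each forest's target.
#' @return list: node_id, rank_before, rank_after, in_window, mda_before,
#'   mda_after, mass_before, mass_after.
#' @export
spike_redistribution_test <- function(features, metadata,
                                      source_target = "age",
                                      spike_target = "genotype",
                                      group_level = "WT", node_id = NULL,
                                      rank_window = 20, n_trees = 1000,
                                      seed = NULL, covariates = NULL) {
  metadata <- align_metadata(features, metadata)
  covs <- function(target) {
    if (!is.null(covariates)) setdiff(covariates, target)
    else setdiff(intersect(c("niche", "age", "genotype"), colnames(metadata)),
                 target)
  }
  if (is.null(node_id)) {
    src <- fit_criterion_forest(features, metadata,
                                forest_config(source_target, covs(source_target),
                                              n_trees = n_trees, seed = seed))
    node_id <- top_important_clades(src, k = 1)$clade_id
  }
  mask <- metadata[[spike_target]] == group_level
  if (!any(mask)) stop("no samples with ", spike_target, " = ", group_level)
  cfg <- forest_config(spike_target, covs(spike_target), n_trees = n_trees,
                       seed = seed)
  before <- fit_criterion_forest(features, metadata, cfg)
  spiked <- spike_redistribute(features, node_id, mask)
  after <- fit_criterion_forest(spiked, metadata, cfg)
  list(node_id = node_id,
       rank_before = clade_mda_rank(before, node_id),
       rank_after = clade_mda_rank(after, node_id),
       in_window = clade_mda_rank(after, node_id) <= rank_window,
       mda_before = unname(before$mda[node_id]),
       mda_after = unname(after$mda[node_id]),
       mass_before = sum(features[, node_id]),
       mass_after = sum(spiked[, node_id]))
}

#' MDA reproducibility versus forest size
#'
#' For each forest size, fits the same forest under \code{n_seeds} different
#' seeds and averages the pairwise Spearman rank correlations of the clade
#' MDA vectors. Ranking reproducibility should saturate with forest size
#' (see \code{\link{fit_monod}}).
#'
#' @param features clade abundance matrix.
#' @param metadata sample metadata.
#' @param target criterion to predict.
#' @param sizes ascending forest sizes.
#' @param n_seeds seeds per size (default 3).
#' @param covariates covariate columns (default none).
#' @param base_seed first seed; seeds are \code{base_seed + 0:(n_seeds-1)}.
#' @return data.frame: size, mean_spearman (class \code{cf_treesize}); the
#'   per-pair correlations are kept in \code{attr(, "pairs")}.
#' @export
forest_size_reproducibility <- function(features, metadata, target,
                                        sizes = c(50, 200, 1000, 5000),
                                        n_seeds = 3, covariates = character(),
                                        base_seed = 1) {
  if (any(sizes < 1)) stop("forest sizes must be >= 1")
  if (is.unsorted(sizes)) stop("sizes must be ascending")
  if (n_seeds < 2) stop("need >= 2 seeds")
  pairs <- list()
  out <- data.frame(size = sizes, mean_spearman = NA_real_)
  for (i in seq_along(sizes)) {
    mdas <- lapply(seq_len(n_seeds) - 1L, function(k) {
      r <- fit_criterion_forest(features, metadata,
                                forest_config(target, covariates,
                                              n_trees = sizes[i],
                                              seed = base_seed + k))
      r$mda[r$is_clade]
    })
    rho <- utils::combn(n_seeds, 2, function(ix)
      stats::cor(mdas[[ix[1]]], mdas[[ix[2]]], method = "spearman"))
    out$mean_spearman[i] <- mean(rho)
    pairs[[i]] <- rho
  }
  attr(out, "pairs") <- pairs
  class(out) <- c("cf_treesize", "data.frame")
  out
}

#' Fit a Monod / Michaelis-Menten saturation curve
#'
#' Nonlinear least squares of \eqn{r(n) = a n / (b + n)} to (forest size,
#' mean MDA correlation) pairs, initialized at \code{a = max(r)},
#' \code{b = median(n)}. The asymptote \code{a} is constrained to [-1, 1]
#' (it is a correlation) and \code{b > 0}; a fit pinned at the lower
#' \code{b} boundary (degenerate, constant data) is flagged.
#'
#' @param sizes positive forest sizes (>= 3 values).
#' @param correlations corresponding correlations.
#' @return object of class \code{monod_fit}: \code{a}, \code{b}, \code{rss},
#'   \code{boundary}, \code{fitted} (function of n).
#' @export
fit_monod <- function(sizes, correlations) {
  if (length(sizes) < 3 || length(sizes) != length(correlations))
    stop("need >= 3 (size, correlation) pairs")
  if (any(sizes <= 0)) stop("sizes must be positive")
  df <- data.frame(n = as.numeric(sizes), r = as.numeric(correlations))
  if (stats::var(df$r) < 1e-12) {
    # constant correlations: the curve degenerates to r = a with b -> 0
    a <- mean(df$r)
    return(structure(list(a = a, b = 1e-9,
                          rss = sum((df$r - a)^2), boundary = TRUE,
                          fitted = function(n) a * n / (1e-9 + n),
                          data = df), class = "monod_fit"))
  }
  start <- list(a = max(df$r), b = stats::median(df$n))
  fit <- tryCatch(
    minpack.lm::nlsLM(r ~ a * n / (b + n), data = df, start = start,
                      lower = c(a = -1, b = 1e-9), upper = c(a = 1, b = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("Monod fit did not converge (start a = ",
                             signif(start$a, 4), ", b = ", signif(start$b, 4),
                             "): ", conditionMessage(e)))
  co <- stats::coef(fit)
  structure(list(a = unname(co["a"]), b = unname(co["b"]),
                 rss = sum(stats::residuals(fit)^2),
                 boundary = unname(co["b"] <= 1e-6),
                 fitted = function(n) unname(co["a"]) * n / (unname(co["b"]) + n),
                 data = df), class = "monod_fit")
}

#' @export
print.monod_fit <- function(x, ...) {
  cat(sprintf("Monod fit: r(n) = %.4f * n / (%.4g + n), RSS = %.3g%s\n",
              x$a, x$b, x$rss,
              if (x$boundary) " [b at lower boundary: degenerate]" else ""))
  invisible(x)
}

#' Technical-replicate consistency of a forest
#'
#' Given several technical replicate samples of one underlying specimen
#' (flagged in \code{metadata[[replicate_var]]} with a shared label, NA for
#' ordinary samples), refits the forest once per replicate -- each time the
#' replicate stands in for the specimen alongside all ordinary samples -- and
#' reports per-replicate OOB accuracy plus pairwise Spearman correlations of
#' the clade MDA vectors.
#'
#' @param features clade abundance matrix including the replicate rows.
#' @param metadata sample metadata; replicate rows must agree on every column
#'   except the sample id and \code{replicate_var}.
#' @param target criterion to predict.
#' @param replicate_var metadata column flagging replicates (default
#'   \code{"replicate_of"}).
#' @param covariates covariate columns.
#' @param n_trees,seed forest parameters.
#' @return list: \code{per_replicate} (data.frame replicate id, oob_accuracy),
#'   \code{mda_cor} (pairwise Spearman matrix), \code{mean_correlation}.
#' @export
replicate_consistency <- function(features, metadata, target,
                                  replicate_var = "replicate_of",
                                  covariates = character(), n_trees = 1000,
                                  seed = NULL) {
  metadata <- align_metadata(features, metadata)
  if (!replicate_var %in% colnames(metadata))
    stop("metadata lacks column '", replicate_var, "'")
  rep_ix <- which(!is.na(metadata[[replicate_var]]))
  if (length(rep_ix) < 2) stop("need >= 2 flagged technical replicates")
  if (length(unique(metadata[[replicate_var]][rep_ix])) != 1)
    stop("replicates of more than one specimen; run one group at a time")
  chk <- metadata[rep_ix, setdiff(colnames(metadata),
                                  c("sample_id", replicate_var)), drop = FALSE]
  if (nrow(unique(chk)) != 1)
    stop("replicate rows disagree on metadata columns: ",
         paste(colnames(chk)[vapply(chk, function(v) length(unique(v)) > 1,
                                    logical(1))], collapse = ", "))
  base_ix <- setdiff(seq_len(nrow(metadata)), rep_ix)
  cfg <- forest_config(target, covariates, n_trees = n_trees, seed = seed)
  fits <- lapply(rep_ix, function(r) {
    ix <- c(base_ix, r)
    fit_criterion_forest(features[ix, , drop = FALSE],
                         metadata[ix, , drop = FALSE], cfg)
  })
  ids <- rownames(metadata)[rep_ix]
  mdas <- vapply(fits, function(f) f$mda[f$is_clade],
                 numeric(sum(fits[[1]]$is_clade)))
  colnames(mdas) <- ids
  mda_cor <- stats::cor(mdas, method = "spearman")
  list(per_replicate = data.frame(
         replicate = ids,
         oob_accuracy = vapply(fits, function(f) f$oob_accuracy, numeric(1)),
         stringsAsFactors = FALSE),
       mda_cor = mda_cor,
       mean_correlation = mean(mda_cor[lower.tri(mda_cor)]))
}

#' Spearman correlation of importances across two forests
#'
#' Rank correlation of the clade MDA vectors of two forests (e.g. cage vs
#' mother), optionally referenced against the correlations observed among
#' pairs of null forests.
#'
#' @param a,b \code{forest_result}s sharing one clade feature set.
#' @param null_pairs optional list of 2-element lists of null
#'   \code{forest_result}s providing the null correlation distribution.
#' @return list: \code{rho}, \code{null_rho} (numeric vector, possibly empty).
#' @export
cross_forest_importance_correlation <- function(a, b, null_pairs = NULL) {
  stopifnot(inherits(a, "forest_result"), inherits(b, "forest_result"))
  ca <- a$feature_ids[a$is_clade]; cb <- b$feature_ids[b$is_clade]
  if (!identical(ca, cb)) stop("forests have different clade feature sets")
  rho <- stats::cor(a$mda[ca], b$mda[cb], method = "spearman")
  null_rho <- numeric(0)
  if (!is.null(null_pairs)) {
    null_rho <- vapply(null_pairs, function(p) {
      c1 <- p[[1]]$feature_ids[p[[1]]$is_clade]
      stats::cor(p[[1]]$mda[c1], p[[2]]$mda[c1], method = "spearman")
    }, numeric(1))
  }
  list(rho = rho, null_rho = null_rho)
}
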