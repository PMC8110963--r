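#' Importance versus phylogenetic scale or abundance
#'
#' Pairs each clade's MDA with a scale axis (tree depth, branch-length
#' distance from the root, or total descendant tip count), for a real forest
#' and its permutation-null control, and smooths both with locally weighted
#' regression of MDA on log10(axis + offset). Pointwise confidence bands come
#' from bootstrap resampling of clades. Raw points are retained; smoothing is
#' reproducible given the seed.
#'
#' @param real,null \code{forest_result}s on the same clade feature set.
#' @param annotations data.frame from \code{\link{annotate_clades}} covering
#'   every clade feature.
#' @param axis one of \code{"depth"}, \code{"root_distance"},
#'   \code{"total_tips"}.
#' @param span loess span (default 0.75).
#' @param n_boot bootstrap resamples for the confidence band (default 200).
#' @param conf band coverage (default 0.95).
#' @param n_grid evaluation grid size.
#' @param log_offset added before log10 so a zero axis value (the root's
#'   depth) stays finite.
#' @param seed integer seed for the bootstrap.
#' @return object of class \code{scale_profile}: \code{points} (clade_id, x,
#'   log_x, mda_real, mda_null), \code{grid} (log_x, x, real, real_lo,
#'   real_hi, null, null_lo, null_hi), plus the smoothing parameters.
#' @export
importance_scale_profile <- function(real, null, annotations,
                                     axis = c("depth", "root_distance",
                                              "total_tips"),
                                     span = 0.75, n_boot = 200, conf = 0.95,
                                     n_grid = 80, log_offset = 1,
                                     seed = NULL) {
  axis <- match.arg(axis)
  stopifnot(inherits(real, "forest_result"), inherits(null, "forest_result"))
  clades <- real$feature_ids[real$is_clade]
  if (!identical(clades, null$feature_ids[null$is_clade]))
    stop("real and null forests have different clade feature sets")
  miss <- setdiff(clades, annotations$node_id)
  if (length(miss)) stop("annotations missing clade(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  ann <- annotations[match(clades, annotations$node_id), ]
  x <- ann[[axis]]
  if (axis == "root_distance" && anyNA(x))
    stop("root_distance unavailable: tree has no branch lengths")
  lx <- log10(x + log_offset)
  pts <- data.frame(clade_id = clades, x = x, log_x = lx,
                    mda_real = unname(real$mda[clades]),
                    mda_null = unname(null$mda[clades]),
                    stringsAsFactors = FALSE)
  if (!is.null(seed)) set.seed(seed)
  grid_lx <- seq(min(lx), max(lx), length.out = n_grid)
  sm_real <- smooth_with_band(lx, pts$mda_real, grid_lx, span, n_boot, conf)
  sm_null <- smooth_with_band(lx, pts$mda_null, grid_lx, span, n_boot, conf)
  grid <- data.frame(log_x = grid_lx, x = 10^grid_lx - log_offset,
                     real = sm_real$fit, real_lo = sm_real$lo,
                     real_hi = sm_real$hi, null = sm_null$fit,
                     null_lo = sm_null$lo, null_hi = sm_null$hi)
  structure(list(axis = axis, points = pts, grid = grid, span = span,
                 n_boot = n_boot, conf = conf, log_offset = log_offset),
            class = "scale_profile")
}

smooth_with_band <- function(x, y, grid, span, n_boot, conf) {
  fit_once <- function(xi, yi) {
    fit <- suppressWarnings(stats::loess(yi ~ xi, span = span, degree = 1,
                                         family = "gaussian",
                                         control = stats::loess.control(surface = "direct")))
    suppressWarnings(stats::predict(fit, newdata = data.frame(xi = grid)))
  }
  fit <- fit_once(x, y)
  boots <- matrix(NA_real_, n_boot, length(grid))
  n <- length(x)
  for (b in seq_len(n_boot)) {
    ix <- sample.int(n, n, replace = TRUE)
    boots[b, ] <- tryCatch(fit_once(x[ix], y[ix]),
                           error = function(e) rep(NA_real_, length(grid)))
  }
  alpha <- (1 - conf) / 2
  list(fit = fit,
       lo = apply(boots, 2, stats::quantile, probs = alpha, na.rm = TRUE),
       hi = apply(boots, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE))
}

#' Real-minus-null separation along a scale profile
#'
#' Convenience summary of where the real forest's smoothed importance curve
#' exceeds the null's: the pointwise difference of the smoothed means and a
#' flag for grid points where the real curve lies above the null's upper
#' confidence bound.
#'
#' @param profile a \code{scale_profile}.
#' @return data.frame: x, log_x, separation (real minus null smoothed mean),
#'   beyond_null_band (real mean curve above the null band's upper bound) and
#'   bands_overlap (the two confidence bands intersect).
#' @export
profile_separation <- function(profile) {
  stopifnot(inherits(profile, "scale_profile"))
  g <- profile$grid
  data.frame(x = g$x, log_x = g$log_x, separation = g$real - g$null,
             beyond_null_band = g$real > g$null_hi,
             bands_overlap = g$real_lo <= g$null_hi & g$null_lo <= g$real_hi)
}

#' @export
print.scale_profile <- function(x, ...) {
  cat(sprintf("Scale profile (axis = %s, %d clades, span %.2f, %d bootstraps)\n",
              x$axis, nrow(x$points), x$span, x$n_boot))
  sep <- profile_separation(x)
  cat(sprintf("  mean real - null separation: %.4g (max %.4g at %s = %.3g)\n",
              mean(sep$separation), max(sep$separation), x$axis,
              sep$x[which.max(sep$separation)]))
  invisible(x)
}

#' @export
plot.scale_profile <- function(x, pseudo_log_mda = TRUE, mda_scale = NULL, ...) {
  pts <- x$points; g <- x$grid
  tr <- if (pseudo_log_mda) {
    s <- mda_scale %||% max(stats::sd(pts$mda_real), 1e-8)
    function(v) asinh(v / s)
  } else identity
  yl <- range(tr(c(pts$mda_real, pts$mda_null)), na.rm = TRUE)
  graphics::plot(pts$log_x, tr(pts$mda_real), pch = 16, cex = 0.4,
       col = grDevices::adjustcolor("steelblue", 0.4),
       xlab = sprintf("log10(%s + %g)", x$axis, x$log_offset),
       ylab = if (pseudo_log_mda) "MDA (pseudo-log)" else "MDA",
       ylim = yl, ...)
  graphics::points(pts$log_x, tr(pts$mda_null), pch = 16, cex = 0.4,
                   col = grDevices::adjustcolor("firebrick", 0.3))
  graphics::polygon(c(g$log_x, rev(g$log_x)), tr(c(g$real_lo, rev(g$real_hi))),
                    border = NA, col = grDevices::adjustcolor("steelblue", 0.2))
  graphics::polygon(c(g$log_x, rev(g$log_x)), tr(c(g$null_lo, rev(g$null_hi))),
                    border = NA, col = grDevices::adjustcolor("firebrick", 0.2))
  graphics::lines(g$log_x, tr(g$real), col = "steelblue", lwd = 2)
  graphics::lines(g$log_x, tr(g$null), col = "firebrick", lwd = 2)
  graphics::rug(pts$log_x)
  invisible(x)
}
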