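#' Bray-Curtis dissimilarity among samples
#'
#' \eqn{d(u, v) = \sum |u_i - v_i| / \sum (u_i + v_i)} over the feature
#' columns, computed with \code{vegan::vegdist}. Pairs of all-zero rows are
#' undefined and flagged with a warning.
#'
#' @param mat numeric matrix samples x features (e.g. a clade abundance
#'   matrix).
#' @return a \code{dist} object.
#' @export
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need >= 2 samples")
  zero <- rowSums(mat) == 0
  if (any(zero))
    warning("all-zero sample row(s) give undefined pairs: ",
            paste(rownames(mat)[zero], collapse = ", "))
  vegan::vegdist(mat, method = "bray")
}

#' Jaccard distance on presence/absence
#'
#' Features with abundance strictly greater than \code{presence_threshold}
#' count as present; \eqn{d = 1 - |A \cap B| / |A \cup B|}.
#'
#' @inheritParams bray_curtis
#' @param presence_threshold presence cut-off (default 0, i.e. any nonzero
#'   abundance counts).
#' @return a \code{dist} object.
#' @export
jaccard <- function(mat, presence_threshold = 0) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need >= 2 samples")
  pa <- (mat > presence_threshold) * 1
  zero <- rowSums(pa) == 0
  if (any(zero))
    warning("sample row(s) with no present features give undefined pairs: ",
            paste(rownames(mat)[zero], collapse = ", "))
  vegan::vegdist(pa, method = "jaccard", binary = TRUE)
}

#' Non-metric multidimensional scaling
#'
#' Best-of-\code{n_starts} NMDS minimizing Kruskal stress-1 via
#' \code{vegan::monoMDS} (global model, monotone regression on dissimilarity
#' ranks). The first start is initialized from classical scaling, the rest
#' from random configurations. The result records whether the best start
#' converged and whether its stress clears the conventional 0.20
#' acceptability threshold.
#'
#' @param dist a \code{dist} object.
#' @param k embedding dimension (default 2).
#' @param n_starts number of starts (default 20).
#' @param max_iter iteration cap per start.
#' @param sfgrmin,smin convergence tolerances passed to \code{monoMDS}
#'   (scale-factor of the gradient; minimum stress).
#' @param seed integer seed for the random starts.
#' @return object of class \code{cf_nmds}: \code{points} (centred n x k
#'   coordinates), \code{stress}, \code{converged}, \code{acceptable},
#'   \code{n_starts}, \code{stress_all}.
#' @export
nmds <- function(dist, k = 2, n_starts = 20, max_iter = 500,
                 sfgrmin = 1e-7, smin = 1e-8, seed = NULL) {
  n <- attr(dist, "Size")
  if (is.null(n)) stop("dist must be a 'dist' object")
  if (n < k + 1) stop("need at least k + 1 samples")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  stress_all <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    init <- if (s == 1) {
      y <- suppressWarnings(stats::cmdscale(dist, k = k))
      if (ncol(y) < k) cbind(y, matrix(stats::rnorm(n * (k - ncol(y)), 0, 1e-4), n))
      else y
    } else matrix(stats::rnorm(n * k), n, k)
    fit <- vegan::monoMDS(dist, y = init, k = k, model = "global",
                          maxit = max_iter, smin = smin, sfgrmin = sfgrmin,
                          sratmax = 0.999999)
    stress_all[s] <- fit$stress
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  converged <- best$icause != 1L
  if (!converged) warning("no NMDS start converged; returning best effort")
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  dimnames(pts) <- list(attr(dist, "Labels"), paste0("NMDS", seq_len(k)))
  structure(list(points = pts, stress = best$stress, converged = converged,
                 acceptable = best$stress <= 0.20, k = k,
                 n_starts = n_starts, stress_all = stress_all),
            class = "cf_nmds")
}

#' @export
print.cf_nmds <- function(x, ...) {
  cat(sprintf("NMDS (k = %d, %d starts): stress-1 = %.4f (%s the 0.20 acceptability threshold), %s\n",
              x$k, x$n_starts, x$stress,
              if (x$acceptable) "within" else "ABOVE",
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' PERMANOVA on a distance matrix
#'
#' Partitions the distance matrix by the McArdle-Anderson inner-product
#' decomposition with sequential (Type I) sums of squares, assessed by free
#' row permutations, via \code{vegan::adonis2}. The p-value follows the
#' add-one rule \eqn{(1 + \#\{F^* \ge F\}) / (1 + n_{perm})}, so it is never
#' reported as 0. With \code{exact = TRUE} (n <= 7) every relabelling is
#' enumerated, making the p-value the exact permutation probability.
#'
#' @param dist a \code{dist} object.
#' @param metadata data.frame of sample factors, rows matching \code{dist}
#'   labels (reordered by sample id when labels are present).
#' @param formula one-sided formula over metadata columns, interactions
#'   allowed, e.g. \code{~ age * niche * genotype}.
#' @param n_perm number of permutations (>= 99; default 999). Ignored when
#'   \code{exact = TRUE}.
#' @param seed integer seed for the permutations.
#' @param exact enumerate all n! row permutations instead of sampling.
#' @return data.frame (class \code{cf_permanova}) with one row per term plus
#'   Residual and Total: df, SumOfSqs, R2, F, p.
#' @export
permanova <- function(dist, metadata, formula, n_perm = 999, seed = NULL,
                      exact = FALSE) {
  n <- attr(dist, "Size")
  if (is.null(n)) stop("dist must be a 'dist' object")
  if (all(as.vector(dist) == 0)) stop("all distances are zero")
  labs <- attr(dist, "Labels")
  if (!is.null(labs)) {
    ids <- rownames(metadata)
    if (!is.null(ids) && !identical(ids, labs)) {
      if (!setequal(ids, labs))
        stop("metadata rows do not match distance matrix ids")
      metadata <- metadata[labs, , drop = FALSE]
    }
  }
  if (nrow(metadata) != n) stop("metadata rows do not match distance matrix")
  vars <- all.vars(formula)
  miss <- setdiff(vars, colnames(metadata))
  if (length(miss)) stop("formula variable(s) missing from metadata: ",
                         paste(miss, collapse = ", "))
  for (v in vars) {
    if (length(unique(metadata[[v]])) < 2)
      stop("factor '", v, "' is constant")
  }
  if (!exact && n_perm < 99) stop("n_perm must be >= 99")
  if (!is.null(seed)) set.seed(seed)
  if (exact) {
    if (n > 7) stop("exact enumeration limited to n <= 7 samples")
    perms <- all_permutations(n)
    perms <- perms[rowSums(perms == rep(seq_len(n), each = nrow(perms))) != n,
                   , drop = FALSE]
    permarg <- perms
  } else {
    permarg <- n_perm
  }
  d <- dist
  f <- stats::as.formula(call("~", quote(d), formula[[2]]))
  environment(f) <- environment()
  res <- vegan::adonis2(f, data = metadata, permutations = permarg,
                        by = "terms")
  out <- data.frame(term = rownames(res), df = res$Df,
                    SumOfSqs = res$SumOfSqs, R2 = res$R2, F = res$F,
                    p = res$`Pr(>F)`, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("cf_permanova", "data.frame")
  attr(out, "n_perm") <- if (exact) nrow(permarg) else n_perm
  attr(out, "exact") <- exact
  out
}

# all n! permutations of 1..n as rows (small n only)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                 sub[, seq.int(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}
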