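#' Simulate per-sample tip counts on a tree
#'
#' Draws a heavy-tailed (log-normal) baseline proportion for every tip, shared
#' across samples; overlays maternal and cage structure as additive log-scale
#' random effects on a set of deep clades; multiplies tips under planted
#' effect clades by their fold changes in samples carrying the matching
#' factor level; adds independent per-sample log-normal tip noise; then draws
#' counts multinomially at a sequencing depth sampled from a truncated
#' log-normal whose truncated mean is calibrated to \code{depth_model["mean"]}
#' on \code{[min, max]}.
#'
#' With an empty effect map and \code{mother_sigma = cage_sigma = 0} all group
#' labels are exchangeable: samples differ only by i.i.d. noise and
#' multinomial resampling.
#'
#' @param tree rooted \code{phylo} whose tips index the count columns.
#' @param metadata design table from \code{\link{simulate_design}} (columns
#'   \code{sample_id, cage, mother} and any factors named in \code{effects}).
#' @param effects effect map from \code{\link{plant_effects}} (or NULL).
#' @param depth_model named vector \code{c(mean, min, max)} of sequencing
#'   depth; defaults mirror a mean of 10442 reads ranging 1892--25681.
#' @param depth_sdlog log-sd of the depth distribution.
#' @param baseline_sigma log-sd of the shared baseline tip proportions.
#' @param sample_sigma log-sd of independent per-sample, per-tip noise.
#' @param mother_sigma,cage_sigma log-sd of maternal / cage random effects on
#'   the random-effect clades (0 disables).
#' @param n_re_clades,re_depth_band how many clades carry the cage/mother
#'   random effects and from which depth band they are drawn.
#' @param seed integer seed; identical arguments give identical counts.
#' @return integer matrix samples x tips with sample ids as rownames.
#' @export
simulate_counts <- function(tree, metadata, effects = NULL,
                            depth_model = c(mean = 10442, min = 1892, max = 25681),
                            depth_sdlog = 0.45,
                            baseline_sigma = 2, sample_sigma = 0.5,
                            mother_sigma = 0.6, cage_sigma = 0.4,
                            n_re_clades = 12, re_depth_band = c(1, 4),
                            seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  nsamp <- nrow(metadata)
  if (nsamp < 1) stop("metadata has no rows")
  if (baseline_sigma <= 0) stop("baseline_sigma must be > 0")
  dm <- depth_model
  if (!(dm["min"] <= dm["mean"] && dm["mean"] <= dm["max"]))
    stop("depth_model must satisfy min <= mean <= max")
  if (!is.null(effects) && nrow(effects) > 0) {
    eff_nums <- node_num(effects$clade_id)
    if (!all(eff_nums > ntip & eff_nums <= ntip + tree$Nnode))
      stop("effect clade(s) not internal nodes of the tree")
    miss <- setdiff(effects$factor, colnames(metadata))
    if (length(miss)) stop("effect factor(s) missing from metadata: ",
                           paste(miss, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)

  # shared heavy-tailed baseline
  base_log <- stats::rnorm(ntip, 0, baseline_sigma)

  # cage/mother random effects on deep clades
  use_re <- (mother_sigma > 0 || cage_sigma > 0) && n_re_clades > 0
  re_tips <- list(); mother_eff <- NULL; cage_eff <- NULL
  if (use_re) {
    depth <- node_depths(tree)
    internal <- seq.int(ntip + 1L, ntip + tree$Nnode)
    cand <- internal[depth[internal] >= re_depth_band[1] &
                     depth[internal] <= re_depth_band[2]]
    if (length(cand) == 0)
      stop("no internal clade in re_depth_band [", re_depth_band[1], ", ",
           re_depth_band[2], "]")
    re_nodes <- sample(cand, min(n_re_clades, length(cand)))
    re_tips <- clade_tip_indices(tree, re_nodes)
    mothers <- sort(unique(metadata$mother))
    cages <- sort(unique(metadata$cage))
    mother_eff <- matrix(stats::rnorm(length(mothers) * length(re_nodes),
                                      0, mother_sigma),
                         length(mothers), length(re_nodes),
                         dimnames = list(mothers, NULL))
    cage_eff <- matrix(stats::rnorm(length(cages) * length(re_nodes),
                                    0, cage_sigma),
                       length(cages), length(re_nodes),
                       dimnames = list(cages, NULL))
  }

  eff_tips <- list()
  if (!is.null(effects) && nrow(effects) > 0)
    eff_tips <- clade_tip_indices(tree, node_num(effects$clade_id))

  depths <- rtrunc_lnorm(nsamp, dm["mean"], dm["min"], dm["max"], depth_sdlog)

  counts <- matrix(0L, nsamp, ntip,
                   dimnames = list(metadata$sample_id, tree$tip.label))
  for (s in seq_len(nsamp)) {
    lp <- base_log
    if (use_re) {
      for (j in seq_along(re_tips)) {
        ix <- re_tips[[j]]
        lp[ix] <- lp[ix] + mother_eff[metadata$mother[s], j] +
          cage_eff[metadata$cage[s], j]
      }
    }
    if (length(eff_tips)) {
      for (e in seq_len(nrow(effects))) {
        if (metadata[[effects$factor[e]]][s] == effects$level[e]) {
          ix <- eff_tips[[e]]
          lp[ix] <- lp[ix] + log(effects$fold_change[e])
        }
      }
    }
    if (sample_sigma > 0)
      lp <- lp + stats::rnorm(ntip, 0, sample_sigma)
    p <- exp(lp - max(lp))
    if (!any(p > 0)) stop("degenerate proportions (all zero) in sample ",
                          metadata$sample_id[s])
    counts[s, ] <- stats::rmultinom(1, depths[s], p)[, 1]
  }
  storage.mode(counts) <- "integer"
  counts
}

# truncated log-normal draws whose truncated mean equals `mean`; the
# location parameter is solved in closed form + root finding
rtrunc_lnorm <- function(n, mean, lo, hi, sdlog) {
  tmean <- function(mu) {
    a <- (log(lo) - mu) / sdlog; b <- (log(hi) - mu) / sdlog
    exp(mu + sdlog^2 / 2) * (stats::pnorm(b - sdlog) - stats::pnorm(a - sdlog)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  mu <- stats::uniroot(function(m) tmean(m) - mean,
                       interval = c(log(lo) - 2, log(hi) + 2))$root
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rlnorm(length(todo), mu, sdlog)
    ok <- draw >= lo & draw <= hi
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  round(out)
}
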