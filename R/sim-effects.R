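#' Plant clade-level effects for experimental factors
#'
#' Chooses internal clades of the tree and assigns each a fold change tied to
#' one level of one metadata factor, creating the ground truth that the
#' downstream forests are expected to recover. A factor given
#' \code{n_clades = 0} receives no entries, encoding a factor with no true
#' community effect (the genotype case).
#'
#' @param tree a rooted \code{phylo}.
#' @param factor_specs named list, one element per factor. Each element is a
#'   list with \code{n_clades}, \code{fold_range} (length-2, > 0) and either
#'   \code{depth_band} (inclusive range of edge-count depths from the root)
#'   or explicit \code{clade_ids}. Optional \code{levels} restricts which
#'   factor levels receive effects (default: all levels of the metadata
#'   column, cycled across the chosen clades).
#' @param metadata sample metadata supplying the factor levels.
#' @param seed integer seed for clade selection and fold draws.
#' @return an effect map: data.frame with columns \code{factor, level,
#'   clade_id, fold_change} (zero rows are legitimate).
#' @examples
#' tr <- simulate_tree(50, seed = 1)
#' md <- simulate_design(design_spec())
#' plant_effects(tr, list(niche = list(n_clades = 3, depth_band = c(2, 6),
#'                                     fold_range = c(2, 4)),
#'                        genotype = list(n_clades = 0)),
#'               md, seed = 2)
#' @export
plant_effects <- function(tree, factor_specs, metadata, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), is.list(factor_specs))
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  depth <- node_depths(tree)
  internal <- seq.int(ntip + 1L, ntip + tree$Nnode)
  out <- list()
  for (fac in names(factor_specs)) {
    fs <- factor_specs[[fac]]
    n_clades <- fs$n_clades %||% 0L
    if (n_clades == 0) next
    if (!fac %in% colnames(metadata))
      stop("factor '", fac, "' not present in metadata")
    fold_range <- fs$fold_range %||% c(2, 4)
    if (any(fold_range <= 0)) stop("fold_range must be positive")
    if (!is.null(fs$clade_ids)) {
      nums <- node_num(fs$clade_ids)
      if (!all(nums %in% internal))
        stop("clade_ids outside the tree's internal nodes")
      if (length(nums) != n_clades)
        stop("clade_ids length must equal n_clades")
      picked <- nums
    } else {
      band <- fs$depth_band %||% range(depth[internal])
      cand <- internal[depth[internal] >= band[1] & depth[internal] <= band[2]]
      if (length(cand) == 0)
        stop("no internal clade in depth band [", band[1], ", ", band[2],
             "] for factor '", fac, "'")
      if (length(cand) < n_clades)
        stop("only ", length(cand), " clades in depth band for '", fac,
             "' but n_clades = ", n_clades)
      picked <- sample(cand, n_clades)
    }
    levels <- fs$levels %||% sort(unique(metadata[[fac]]))
    out[[fac]] <- data.frame(
      factor = fac,
      level = rep(levels, length.out = n_clades),
      clade_id = node_id(picked),
      fold_change = stats::runif(n_clades, fold_range[1], fold_range[2]),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(factor = character(), level = character(),
                      clade_id = character(), fold_change = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
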