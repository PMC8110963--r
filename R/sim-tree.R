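#' Simulate a rooted binary phylogeny
#'
#' Generates a pure-birth (Yule) topology and then assigns every edge an
#' independent exponential branch length with mean \code{branch_scale}. The
#' result stands in for an inferred 16S tree: rooted, binary, uniquely
#' labelled tips \code{t1..tN}, positive branch lengths.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed; identical \code{(n_tips, seed, branch_scale)}
#'   give byte-identical newick strings.
#' @param branch_scale mean branch length (> 0).
#' @return an \code{ape} \code{phylo} object.
#' @examples
#' tr <- simulate_tree(16, seed = 1)
#' ape::Ntip(tr)   # 16
#' tr$Nnode        # 15: rooted binary identity
#' @export
simulate_tree <- function(n_tips, seed = NULL, branch_scale = 0.1) {
  if (!is.numeric(n_tips) || length(n_tips) != 1L || n_tips < 2)
    stop("n_tips must be a single integer >= 2")
  if (branch_scale <= 0) stop("branch_scale must be > 0")
  n_tips <- as.integer(n_tips)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1 / branch_scale)
  tree$tip.label <- sprintf("t%d", seq_len(n_tips))
  tree$node.label <- NULL
  tree
}
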