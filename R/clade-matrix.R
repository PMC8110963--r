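#' Read / write a rooted tree
#'
#' Wrappers over \pkg{ape}'s newick parser that verify the tree is rooted and
#' round-trips cleanly. Internal nodes are addressed downstream as
#' \code{N<ape node number>}.
#'
#' @param source newick text or a file path.
#' @return a \code{phylo} object.
#' @export
read_tree <- function(source) {
  tree <- if (file.exists(source)) ape::read.tree(source)
          else ape::read.tree(text = source)
  if (is.null(tree)) stop("newick parse failure in: ",
                          substr(paste(source, collapse = ""), 1, 60))
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  tree
}

#' @rdname read_tree
#' @param tree a \code{phylo}.
#' @param path output file.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Root a tree on an outgroup
#'
#' Reroots so the outgroup tips form one side of the root, the construction
#' used when archaeal reference sequences are added to a bacterial 16S tree.
#' A tree already rooted on the outgroup is returned with its topology
#' unchanged.
#'
#' @param tree a \code{phylo}.
#' @param outgroup_tips tip labels of the outgroup.
#' @return rooted \code{phylo}.
#' @export
root_by_outgroup <- function(tree, outgroup_tips) {
  missing <- setdiff(outgroup_tips, tree$tip.label)
  if (length(missing)) stop("outgroup tip(s) absent from tree: ",
                            paste(missing, collapse = ", "))
  if (length(outgroup_tips) >= ape::Ntip(tree))
    stop("outgroup cannot contain all tips")
  # already rooted on the outgroup: one child subtree of the root holds
  # exactly the outgroup tips -> no-op
  if (ape::is.rooted(tree)) {
    ntip <- ape::Ntip(tree)
    root <- ntip + 1L
    kids <- tree$edge[tree$edge[, 1L] == root, 2L]
    for (k in kids) {
      tips_k <- if (k <= ntip) tree$tip.label[k]
                else tree$tip.label[clade_tip_indices(tree, k)[[1]]]
      if (setequal(tips_k, outgroup_tips)) return(tree)
    }
  }
  rooted <- try(ape::root(tree, outgroup = outgroup_tips,
                          resolve.root = TRUE), silent = TRUE)
  if (inherits(rooted, "try-error") || !ape::is.rooted(rooted))
    stop("outgroup {", paste(outgroup_tips, collapse = ", "),
         "} cannot be separated by a single reroot")
  if (!ape::is.monophyletic(rooted, outgroup_tips))
    stop("outgroup not monophyletic after rerooting; conflicting tips: ",
         paste(outgroup_tips, collapse = ", "))
  rooted
}

#' Clade relative-abundance matrix
#'
#' The core featurization: for every internal node of a rooted tree, the
#' relative abundance of its clade in each sample is (tip counts descending
#' from the node) / (total tip count of the sample). Descendant counts are
#' accumulated in a single postorder pass, in integer arithmetic, and divided
#' by the sample totals at the end. Features are internal nodes only; tips
#' can be appended with \code{include_tips = TRUE} for sensitivity analyses.
#'
#' @param tree rooted \code{phylo}.
#' @param counts integer matrix samples x tips; column names must be a subset
#'   of the tree's tip labels (tree tips absent from \code{counts} contribute
#'   zero).
#' @param include_tips also return tip columns (default FALSE).
#' @return numeric matrix samples x internal nodes, values in [0, 1]; the
#'   root column is identically 1.
#' @examples
#' tr <- read_tree("((A,B)N,C)R;")
#' cm <- clade_abundance_matrix(tr, matrix(c(2, 1, 1), 1, 3,
#'        dimnames = list("s1", c("A", "B", "C"))))
#' cm   # N4 (root) = 1, N5 = 0.75
#' @export
clade_abundance_matrix <- function(tree, counts, include_tips = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) || is.null(rownames(counts)))
    stop("counts needs sample rownames and tip colnames")
  unknown <- setdiff(colnames(counts), tree$tip.label)
  if (length(unknown)) stop("count tips not in tree: ",
                            paste(utils::head(unknown, 5), collapse = ", "))
  totals <- rowSums(counts)
  if (any(totals <= 0)) stop("sample(s) with zero total counts: ",
                             paste(rownames(counts)[totals <= 0], collapse = ", "))
  acc <- clade_counts(tree, counts)
  ntip <- ape::Ntip(tree)
  keep <- seq.int(ntip + 1L, ntip + tree$Nnode)
  if (include_tips) keep <- c(keep, seq_len(ntip))
  rel <- acc[, keep, drop = FALSE] / totals
  cols <- node_id(seq.int(ntip + 1L, ntip + tree$Nnode))
  if (include_tips) cols <- c(cols, tree$tip.label)
  dimnames(rel) <- list(rownames(counts), cols)
  rel
}

# samples x (tips + internal) integer clade counts via postorder accumulation
clade_counts <- function(tree, counts) {
  ntip <- ape::Ntip(tree)
  nsamp <- nrow(counts)
  acc <- matrix(0, nsamp, ntip + tree$Nnode)
  acc[, match(colnames(counts), tree$tip.label)] <- counts
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(edge))) {
    acc[, edge[i, 1L]] <- acc[, edge[i, 1L]] + acc[, edge[i, 2L]]
  }
  acc
}

#' Per-clade scale annotations
#'
#' For every internal node: \code{depth}, the number of edges on the
#' root-to-node path (root = 0); \code{root_distance}, the summed branch
#' length of that path (NA when the tree has no branch lengths);
#' \code{total_tips}, the total number of tip sequences descending from the
#' clade summed over all samples; and \code{n_tree_tips}, the number of tip
#' taxa in the clade.
#'
#' @inheritParams clade_abundance_matrix
#' @return data.frame keyed by \code{node_id}.
#' @export
annotate_clades <- function(tree, counts) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ntip <- ape::Ntip(tree)
  internal <- seq.int(ntip + 1L, ntip + tree$Nnode)
  depth <- node_depths(tree)[internal]
  rd <- node_root_distances(tree)[internal]
  counts <- as.matrix(counts)
  acc <- clade_counts(tree, counts)
  ntips_tree <- clade_counts(tree, matrix(1L, 1, ntip,
                                          dimnames = list("x", tree$tip.label)))
  data.frame(node_id = node_id(internal), depth = depth, root_distance = rd,
             total_tips = colSums(acc[, internal, drop = FALSE]),
             n_tree_tips = as.integer(ntips_tree[1, internal]),
             row.names = node_id(internal), stringsAsFactors = FALSE)
}

#' Finest common taxon of a clade
#'
#' Walks a rank-ordered lineage table from the finest rank upward and returns
#' the deepest rank at which every mapped descendant tip of the node carries
#' the same (non-missing) name, prefixed with the rank's initial (e.g.
#' \code{g_Bacteroides}, \code{f_Lachnospiraceae}). Tips absent from the
#' lineage map are skipped with a warning; if no tip maps, the label is
#' \code{"unclassified"}.
#'
#' @param tree rooted \code{phylo}.
#' @param node internal node id (\code{"N<k>"}).
#' @param taxonomy data.frame with a \code{tip_id} column plus lineage
#'   columns ordered coarse to fine (default ranks kingdom..genus).
#' @param ranks lineage column names, coarse to fine.
#' @return character label.
#' @export
finest_common_taxon <- function(tree, node, taxonomy,
                                ranks = c("kingdom", "phylum", "class",
                                          "order", "family", "genus")) {
  stopifnot(inherits(tree, "phylo"), "tip_id" %in% colnames(taxonomy))
  ranks <- intersect(ranks, colnames(taxonomy))
  if (!length(ranks)) stop("taxonomy has none of the requested rank columns")
  tips <- tree$tip.label[clade_tip_indices(tree, node_num(node))[[1]]]
  hit <- match(tips, taxonomy$tip_id)
  n_unmapped <- sum(is.na(hit))
  if (n_unmapped > 0)
    warning(n_unmapped, " descendant tip(s) missing from the taxonomy map")
  hit <- hit[!is.na(hit)]
  if (!length(hit)) return("unclassified")
  for (r in rev(ranks)) {
    vals <- taxonomy[[r]][hit]
    if (!anyNA(vals) && length(unique(vals)) == 1L)
      return(sprintf("%s_%s", substr(r, 1, 1), vals[1]))
  }
  "unclassified"
}
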