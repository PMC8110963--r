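# Internal helpers shared by the simulation and featurization code.
# Internal nodes are identified throughout as "N<number>" where <number> is
# the ape node index (Ntip+1 .. Ntip+Nnode), so ids are stable for a given
# newick string read with ape.

node_id <- function(num) sprintf("N%d", num)

node_num <- function(id) {
  num <- suppressWarnings(as.integer(sub("^N", "", id)))
  if (anyNA(num)) stop("malformed internal node id(s): ",
                       paste(id[is.na(num)], collapse = ", "))
  num
}

internal_node_ids <- function(tree) {
  ntip <- ape::Ntip(tree)
  node_id(seq.int(ntip + 1L, ntip + tree$Nnode))
}

# depth (edges from root) and cumulative branch length from root for every
# node, tips included; single preorder pass over the edge matrix
node_depths <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  depth <- integer(nn)
  for (i in seq_len(nrow(edge))) {
    depth[edge[i, 2L]] <- depth[edge[i, 1L]] + 1L
  }
  depth
}

node_root_distances <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  if (is.null(tree$edge.length)) return(rep(NA_real_, nn))
  tr <- ape::reorder.phylo(tree, "cladewise")
  dist <- numeric(nn)
  for (i in seq_len(nrow(tr$edge))) {
    dist[tr$edge[i, 2L]] <- dist[tr$edge[i, 1L]] + tr$edge.length[i]
  }
  dist
}

# tip indices descending from each requested internal node number;
# iterative stack walk over a child list built once
clade_tip_indices <- function(tree, node_nums) {
  ntip <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  lapply(node_nums, function(nd) {
    out <- integer(0)
    stack <- nd
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (v <= ntip) {
        out <- c(out, v)
      } else {
        stack <- c(stack, kids[[as.character(v)]])
      }
    }
    sort(out)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
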