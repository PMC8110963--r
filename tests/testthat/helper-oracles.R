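# Shared fixtures and independent oracles.

# random rooted tree + random integer counts for property tests
random_tree_counts <- function(n_tips, n_samples = 4, max_count = 20) {
  tree <- simulate_tree(n_tips, seed = NULL)
  counts <- matrix(sample.int(max_count + 1L, n_samples * n_tips,
                              replace = TRUE) - 1L,
                   n_samples, n_tips,
                   dimnames = list(sprintf("s%d", seq_len(n_samples)),
                                   tree$tip.label))
  # ensure positive totals
  counts[, 1] <- counts[, 1] + 1L
  list(tree = tree, counts = counts)
}

# oracle clade counts: enumerate each internal node's descendant tips with
# phangorn (a code path independent of the package's postorder accumulation)
oracle_clade_matrix <- function(tree, counts) {
  ntip <- ape::Ntip(tree)
  internal <- seq.int(ntip + 1L, ntip + tree$Nnode)
  desc <- phangorn::Descendants(tree, internal, type = "tips")
  out <- sapply(seq_along(internal), function(i) {
    tips <- tree$tip.label[desc[[i]]]
    rowSums(counts[, intersect(tips, colnames(counts)), drop = FALSE])
  })
  dimnames(out) <- list(rownames(counts), sprintf("N%d", internal))
  out / rowSums(counts)
}

# oracle pseudo-F for a one-factor PERMANOVA straight from pairwise distances
oracle_pseudo_f <- function(dmat, labels) {
  n <- nrow(dmat)
  sst <- sum(dmat[lower.tri(dmat)]^2) / n
  ssw <- 0
  for (g in unique(labels)) {
    ix <- which(labels == g)
    sub <- dmat[ix, ix, drop = FALSE]
    ssw <- ssw + sum(sub[lower.tri(sub)]^2) / length(ix)
  }
  ssa <- sst - ssw
  df1 <- length(unique(labels)) - 1
  (ssa / df1) / (ssw / (n - df1 - 1))
}

# first internal node at a given depth (edges from root)
internal_id_at_depth <- function(tree, d) {
  depths <- cladeforest:::node_depths(tree)
  ntip <- ape::Ntip(tree)
  internal <- seq.int(ntip + 1L, ntip + tree$Nnode)
  cand <- internal[depths[internal] == d]
  stopifnot(length(cand) > 0)
  sprintf("N%d", cand[1])
}

# tiny aligned-FASTA fixture
toy_alignment <- function() {
  c(a1 = "--AC-G--",
    a2 = "ACGTACGT",
    a3 = "--------",
    a4 = ".AC.GTA.")
}

# small planted-effect dataset reused by several forest tests
planted_dataset <- function(n_tips = 150, fold = 4, seed = 11) {
  tree <- simulate_tree(n_tips, seed = seed)
  md <- simulate_design(design_spec())
  eff <- plant_effects(tree, list(
    niche = list(n_clades = 5, depth_band = c(4, 8),
                 fold_range = c(fold, fold)),
    age = list(n_clades = 5, depth_band = c(4, 8),
               fold_range = c(2, 4))), md, seed = seed + 1)
  counts <- simulate_counts(tree, md, eff, seed = seed + 2)
  list(tree = tree, metadata = md, effects = eff, counts = counts,
       cm = clade_abundance_matrix(tree, counts))
}
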