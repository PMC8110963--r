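test_that("read_tree parses newick and flags failures", {
  tr <- read_tree("((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(tr$Nnode, 2)
  expect_identical(ape::write.tree(read_tree(ape::write.tree(tr))),
                   ape::write.tree(tr))   # round-trip

  nolen <- read_tree("(A,B);")
  expect_null(nolen$edge.length)
  ann <- annotate_clades(nolen, matrix(c(1L, 1L), 1, 2,
                                       dimnames = list("s1", c("A", "B"))))
  expect_true(all(is.na(ann$root_distance)))  # unavailable, not zero

  expect_error(suppressWarnings(read_tree("((A,B;")))
})

test_that("root_by_outgroup separates the outgroup and is idempotent", {
  tr <- read_tree("(((b1:1,b2:1):1,(b3:1,b4:1):1):1,(arc1:1,(arc2:1,arc3:1):1):1);")
  outg <- c("arc1", "arc2", "arc3")
  rooted <- root_by_outgroup(ape::unroot(tr), outg)
  expect_true(ape::is.rooted(rooted))
  expect_true(ape::is.monophyletic(rooted, outg))
  # outgroup is one side of the root
  root <- ape::Ntip(rooted) + 1L
  kids <- rooted$edge[rooted$edge[, 1] == root, 2]
  sides <- lapply(kids, function(k)
    if (k <= ape::Ntip(rooted)) rooted$tip.label[k]
    else ape::extract.clade(rooted, k)$tip.label)
  expect_true(any(vapply(sides, setequal, logical(1), outg)))
  # idempotence on an already-correctly-rooted tree
  expect_identical(ape::write.tree(root_by_outgroup(rooted, outg)),
                   ape::write.tree(rooted))

  expect_error(root_by_outgroup(tr, tr$tip.label), "all tips")
  expect_error(root_by_outgroup(tr, c("arc1", "zz")), "absent")
})

test_that("clade abundances match the hand oracle on the toy tree", {
  tr <- read_tree("((A,B),C);")
  counts <- matrix(c(2L, 1L, 1L), 1, 3,
                   dimnames = list("s1", c("A", "B", "C")))
  cm <- clade_abundance_matrix(tr, counts)
  expect_equal(cm["s1", "N4"], 1.0)    # root normalization
  expect_equal(cm["s1", "N5"], 0.75)   # (2+1)/4

  # a tip absent from a sample contributes zero to its ancestors
  c2 <- matrix(c(0L, 0L, 3L), 1, 3, dimnames = list("s1", c("A", "B", "C")))
  cm2 <- clade_abundance_matrix(tr, c2)
  expect_equal(cm2["s1", "N5"], 0)
  expect_equal(cm2["s1", "N4"], 1.0)

  expect_error(clade_abundance_matrix(tr, counts * 0L), "zero total")
  bad <- counts; colnames(bad) <- c("A", "B", "Z")
  expect_error(clade_abundance_matrix(tr, bad), "not in tree")
})

test_that("children partition the parent's clade counts (conservation)", {
  set.seed(99)
  for (rep in 1:10) {
    rc <- random_tree_counts(n_tips = sample(5:30, 1))
    cm <- clade_abundance_matrix(rc$tree, rc$counts, include_tips = TRUE)
    tree <- rc$tree
    ntip <- ape::Ntip(tree)
    for (parent in seq.int(ntip + 1L, ntip + tree$Nnode)) {
      kids <- tree$edge[tree$edge[, 1] == parent, 2]
      kid_ids <- ifelse(kids <= ntip, tree$tip.label[kids],
                        sprintf("N%d", kids))
      expect_equal(rowSums(cm[, kid_ids, drop = FALSE]),
                   cm[, sprintf("N%d", parent)])
    }
  }
})

test_that("clade annotations use the edge-count depth convention", {
  tr <- read_tree("((A:1,B:1):2,C:3);")
  counts <- matrix(c(2L, 1L, 1L), 1, 3,
                   dimnames = list("s1", c("A", "B", "C")))
  ann <- annotate_clades(tr, counts)
  expect_equal(ann["N4", "depth"], 0)          # root
  expect_equal(ann["N5", "depth"], 1)
  expect_equal(ann["N4", "root_distance"], 0)
  expect_equal(ann["N5", "root_distance"], 2)  # path sum
  expect_equal(ann["N4", "total_tips"], sum(counts))  # grand total
  expect_equal(ann["N5", "n_tree_tips"], 2L)
})

test_that("finest_common_taxon walks lineages to the shared rank", {
  tr <- read_tree("(((g1,g2),g3),(x1,x2));")
  tax <- data.frame(
    tip_id = c("g1", "g2", "g3", "x1", "x2"),
    kingdom = "Bacteria",
    phylum = c("Bacteroidetes", "Bacteroidetes", "Bacteroidetes",
               "Firmicutes", "Bacteroidetes"),
    family = c("Bacteroidaceae", "Bacteroidaceae", "Bacteroidaceae",
               "Lachnospiraceae", "Porphyromonadaceae"),
    genus = c("Bacteroides", "Bacteroides", "Alistipes",
              "Blautia", "Porphyromonas"),
    stringsAsFactors = FALSE)
  ntip <- 5
  mrca_g12 <- ape::getMRCA(tr, c("g1", "g2"))
  mrca_g123 <- ape::getMRCA(tr, c("g1", "g3"))
  root <- ntip + 1
  expect_equal(finest_common_taxon(tr, sprintf("N%d", mrca_g12), tax),
               "g_Bacteroides")                 # one genus
  expect_equal(finest_common_taxon(tr, sprintf("N%d", mrca_g123), tax),
               "f_Bacteroidaceae")              # two genera, one family
  expect_equal(finest_common_taxon(tr, sprintf("N%d", root), tax),
               "k_Bacteria")                    # two phyla
  expect_warning(
    lbl <- finest_common_taxon(tr, sprintf("N%d", mrca_g12),
                               tax[tax$tip_id != "g1", ]),
    "missing")
  expect_equal(lbl, "g_Bacteroides")
  expect_equal(suppressWarnings(
    finest_common_taxon(tr, sprintf("N%d", mrca_g12), tax[0, ])),
    "unclassified")
})
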