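Package: cladeforest
Title: Phylogeny-Wide Clade Features for Random-Forest Discrimination of
    Microbiome Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns a rooted 16S phylogeny plus per-sample tip counts into a
    relative-abundance matrix over every internal clade and uses it to ask
    which experimental criteria (gut niche, host age, genotype, cage, mother)
    a microbial community discriminates. Provides per-criterion random
    forests controlled for the other treatments, a within-sample permutation
    null forest as negative control, mean-decrease-in-accuracy importance
    profiling against phylogenetic scale and clade abundance, Bray-Curtis and
    Jaccard ordination with PERMANOVA, a validation suite (abundance
    redistribution spike test, forest-size reproducibility with a Monod fit,
    technical-replicate consistency, cross-forest importance correlation),
    alignment trimming and contiguous-length filtering for aligned 16S reads,
    and a seeded synthetic-data generator emulating a mixed-genotype,
    co-housed mouse design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    randomForest,
    minpack.lm,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
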