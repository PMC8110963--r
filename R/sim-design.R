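#' Specify a mouse-cage experimental design
#'
#' Describes the factorial structure the synthetic generator emulates: mice of
#' two genotypes co-housed in mixed-genotype cages nested in mothers, each
#' mouse sampled at exactly one age and in every gut niche. Defaults
#' reproduce the study design: 20 mice, WT/KO, ages 6 and 18 weeks (different
#' mice at each age), stool and mucus niches, 8 cages from 5 mothers.
#'
#' @param n_mice number of mice.
#' @param genotype_levels two or more genotype labels.
#' @param ages age labels; each mouse gets exactly one.
#' @param niches niche labels; each mouse yields one sample per niche.
#' @param n_cages number of cages (>= n_mothers).
#' @param n_mothers number of mothers (>= 1).
#' @param seed kept with the spec for provenance records; the design layout
#'   itself is deterministic.
#' @return a \code{design_spec} list.
#' @export
design_spec <- function(n_mice = 20, genotype_levels = c("WT", "KO"),
                        ages = c("6wk", "18wk"), niches = c("stool", "mucus"),
                        n_cages = 8, n_mothers = 5, seed = NULL) {
  if (n_mothers < 1) stop("n_mothers must be >= 1")
  if (n_cages < n_mothers) stop("n_cages must be >= n_mothers")
  if (n_mice < 1) stop("n_mice must be >= 1")
  if (length(genotype_levels) < 2 || length(ages) < 1 || length(niches) < 1)
    stop("need >= 2 genotypes, >= 1 age and >= 1 niche")
  structure(list(n_mice = as.integer(n_mice),
                 genotype_levels = genotype_levels, ages = ages,
                 niches = niches, n_cages = as.integer(n_cages),
                 n_mothers = as.integer(n_mothers), seed = seed),
            class = "design_spec")
}

#' Lay out sample metadata for a design
#'
#' Builds one metadata row per (mouse, niche). Genotype x age cells are
#' balanced as far as counts allow, mice are dealt round-robin into cages so
#' every cage holds a genotype mix, and cages are nested in mothers (each
#' cage belongs to exactly one mother). The layout is deterministic: the same
#' spec always yields the same table.
#'
#' @param spec a \code{\link{design_spec}}.
#' @return a data.frame with columns \code{sample_id, mouse, niche, age,
#'   genotype, cage, mother}.
#' @examples
#' md <- simulate_design(design_spec())
#' nrow(md)                 # 40 samples
#' table(md$genotype)       # 20 / 20
#' @export
simulate_design <- function(spec = design_spec()) {
  stopifnot(inherits(spec, "design_spec"))
  n <- spec$n_mice
  # balanced genotype x age cells: genotype blocks, age blocks within each
  geno <- rep(spec$genotype_levels,
              each = ceiling(n / length(spec$genotype_levels)))[seq_len(n)]
  age <- character(n)
  for (g in unique(geno)) {
    ix <- which(geno == g)
    age[ix] <- rep(spec$ages,
                   each = ceiling(length(ix) / length(spec$ages)))[seq_along(ix)]
  }
  # round-robin dealing into cages mixes genotypes and ages within cages
  cage <- ((seq_len(n) - 1L) %% spec$n_cages) + 1L
  cage_mother <- ((seq_len(spec$n_cages) - 1L) %% spec$n_mothers) + 1L
  mouse <- sprintf("m%02d", seq_len(n))
  md <- expand.grid(niche = spec$niches, mouse = mouse,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  md <- md[order(md$mouse, md$niche), c("mouse", "niche")]
  ix <- match(md$mouse, mouse)
  md$age <- age[ix]
  md$genotype <- geno[ix]
  md$cage <- sprintf("C%d", cage[ix])
  md$mother <- sprintf("M%d", cage_mother[cage[ix]])
  md$sample_id <- sprintf("%s_%s", md$mouse, md$niche)
  rownames(md) <- md$sample_id
  md[, c("sample_id", "mouse", "niche", "age", "genotype", "cage", "mother")]
}
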