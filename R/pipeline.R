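#' Configure an end-to-end run
#'
#' Bundles the simulation design, planted effects, forest, ordination and
#' profiling parameters with a single global seed from which every stage seed
#' is derived deterministically.
#'
#' Default planted effects mirror the study's qualitative structure: niche
#' and age act on intermediate-depth clades, cage and mother on deeper
#' clades (on top of the generator's cage/mother random effects), genotype
#' carries no community effect at all.
#'
#' @param seed global integer seed.
#' @param n_tips tree size for the simulation.
#' @param design a \code{\link{design_spec}}.
#' @param effect_specs per-factor effect specifications (see
#'   \code{\link{plant_effects}}).
#' @param counts_params extra arguments for \code{\link{simulate_counts}}.
#' @param criteria criteria to model (default niche, age, genotype, cage,
#'   mother).
#' @param n_replicates replicate forests per criterion and arm (default 6).
#' @param n_trees trees per forest.
#' @param n_perm PERMANOVA permutations.
#' @param nmds_starts NMDS random starts.
#' @param profile_axes scale-profile axes to compute.
#' @param profile_boot bootstrap resamples per profile.
#' @param taxonomy optional tip lineage map for clade naming.
#' @return a \code{run_config} list.
#' @export
run_config <- function(seed = 1, n_tips = 500, design = design_spec(),
                       effect_specs = list(
                         niche = list(n_clades = 5, depth_band = c(4, 8),
                                      fold_range = c(2, 4)),
                         age = list(n_clades = 5, depth_band = c(4, 8),
                                    fold_range = c(2, 4)),
                         cage = list(n_clades = 5, depth_band = c(8, 14),
                                     fold_range = c(2, 4)),
                         mother = list(n_clades = 5, depth_band = c(8, 14),
                                       fold_range = c(2, 4)),
                         genotype = list(n_clades = 0)),
                       counts_params = list(),
                       criteria = c("niche", "age", "genotype", "cage",
                                    "mother"),
                       n_replicates = 6, n_trees = 1000, n_perm = 999,
                       nmds_starts = 20,
                       profile_axes = c("depth", "total_tips"),
                       profile_boot = 200, taxonomy = NULL) {
  structure(list(seed = as.integer(seed), n_tips = n_tips, design = design,
                 effect_specs = effect_specs, counts_params = counts_params,
                 criteria = criteria, n_replicates = n_replicates,
                 n_trees = n_trees, n_perm = n_perm,
                 nmds_starts = nmds_starts, profile_axes = profile_axes,
                 profile_boot = profile_boot, taxonomy = taxonomy),
            class = "run_config")
}

stage_seed <- function(seed, k) as.integer((seed + 77003 * k) %% 2147483629L)

#' Run the full analysis pipeline
#'
#' simulate tree/design/effects/counts, featurize, ordinate (Bray-Curtis and
#' Jaccard NMDS + PERMANOVA), fit real and null forests for every criterion
#' over replicate seeds, compare the arms, profile importance against
#' phylogenetic scale and abundance, and write every stage output plus a
#' machine-readable summary to \code{dir}. Identical (config, seed) give an
#' identical summary. A stage failure aborts with the stage name; outputs of
#' completed stages remain on disk.
#'
#' @param config a \code{\link{run_config}}.
#' @param dir output directory (created if needed).
#' @return (invisibly) the summary list; written to \code{summary.json}.
#' @export
run_pipeline <- function(config = run_config(), dir = tempfile("cfrun")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  ver <- as.character(utils::packageVersion("cladeforest"))
  tsv <- function(df, name) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    writeLines(sprintf("# cladeforest %s seed=%d", ver, seed), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    path
  }
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## --- simulate ---
  sim <- stage("simulate", {
    tree <- simulate_tree(config$n_tips, seed = stage_seed(seed, 1))
    # write first, then work from the re-read tree: internal node ids are
    # tied to ape's numbering of a given newick string, so this keeps every
    # on-disk id consistent with the in-memory analysis
    write_tree(tree, file.path(dir, "tree.nwk"))
    tree <- read_tree(file.path(dir, "tree.nwk"))
    metadata <- simulate_design(config$design)
    miss <- setdiff(config$criteria, colnames(metadata))
    if (length(miss)) stop("criteria missing from metadata: ",
                           paste(miss, collapse = ", "))
    effects <- plant_effects(tree, config$effect_specs, metadata,
                             seed = stage_seed(seed, 2))
    counts <- do.call(simulate_counts,
                      c(list(tree = tree, metadata = metadata,
                             effects = effects,
                             seed = stage_seed(seed, 3)),
                        config$counts_params))
    tsv(metadata, "metadata.tsv")
    tsv(effects, "effects.tsv")
    tsv(data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE), "counts.tsv")
    list(tree = tree, metadata = metadata, effects = effects,
         counts = counts)
  })

  ## --- featurize ---
  feat <- stage("featurize", {
    cm <- clade_abundance_matrix(sim$tree, sim$counts)
    ann <- annotate_clades(sim$tree, sim$counts)
    tsv(data.frame(sample_id = rownames(cm), cm, check.names = FALSE),
        "clade_matrix.tsv")
    tsv(ann, "clade_annotations.tsv")
    list(cm = cm, ann = ann)
  })

  ## --- ordinate ---
  ord <- stage("ordinate", {
    fb <- stats::as.formula(paste("~", paste(
      intersect(c("age", "niche", "genotype"), colnames(sim$metadata)),
      collapse = " * ")))
    res <- list()
    for (metric in c("bray", "jaccard")) {
      d <- if (metric == "bray") bray_curtis(feat$cm) else jaccard(feat$cm)
      nm <- nmds(d, k = 2, n_starts = config$nmds_starts,
                 seed = stage_seed(seed, 10))
      pm <- permanova(d, sim$metadata, fb, n_perm = config$n_perm,
                      seed = stage_seed(seed, 11))
      tsv(data.frame(sample_id = rownames(nm$points), nm$points),
          sprintf("nmds_%s.tsv", metric))
      tsv(as.data.frame(pm), sprintf("permanova_%s.tsv", metric))
      res[[metric]] <- list(stress = nm$stress, converged = nm$converged,
                            acceptable = nm$acceptable, permanova = pm)
    }
    res
  })

  ## --- forests (real + null, all criteria, replicated) ---
  forests <- stage("forests", {
    per <- list()
    for (cr in config$criteria) {
      covs <- setdiff(intersect(c("niche", "age", "genotype"),
                                colnames(sim$metadata)), cr)
      reps <- lapply(seq_len(config$n_replicates), function(r) {
        s <- stage_seed(seed, 100 + 10 * match(cr, config$criteria) + r)
        cfg <- forest_config(cr, covs, n_trees = config$n_trees, seed = s)
        list(real = fit_criterion_forest(feat$cm, sim$metadata, cfg),
             null = null_forest(feat$cm, sim$metadata, cfg))
      })
      per[[cr]] <- reps
      acc <- data.frame(
        replicate = seq_along(reps),
        real = vapply(reps, function(x) x$real$oob_accuracy, numeric(1)),
        null = vapply(reps, function(x) x$null$oob_accuracy, numeric(1)))
      tsv(acc, sprintf("forest_accuracy_%s.tsv", cr))
      top <- top_important_clades(reps[[1]]$real, k = 5, tree = sim$tree,
                                  taxonomy = config$taxonomy)
      tsv(top, sprintf("top_clades_%s.tsv", cr))
      tsv(data.frame(feature = names(reps[[1]]$real$mda),
                     mda = unname(reps[[1]]$real$mda),
                     mda_null = unname(reps[[1]]$null$mda)),
          sprintf("mda_%s.tsv", cr))
    }
    per
  })

  comparison <- stage("compare", {
    real <- do.call(rbind, lapply(config$criteria, function(cr)
      data.frame(criterion = cr, accuracy = vapply(
        forests[[cr]], function(x) x$real$oob_accuracy, numeric(1)))))
    null <- do.call(rbind, lapply(config$criteria, function(cr)
      data.frame(criterion = cr, accuracy = vapply(
        forests[[cr]], function(x) x$null$oob_accuracy, numeric(1)))))
    cmp <- compare_real_null_accuracy(real, null)
    tsv(as.data.frame(cmp), "accuracy_comparison.tsv")
    cmp
  })

  ## --- scale profiles ---
  profiles <- stage("profiles", {
    out <- list()
    for (cr in config$criteria) {
      for (ax in config$profile_axes) {
        pr <- importance_scale_profile(
          forests[[cr]][[1]]$real, forests[[cr]][[1]]$null, feat$ann,
          axis = ax, n_boot = config$profile_boot,
          seed = stage_seed(seed, 200 + match(cr, config$criteria)))
        tsv(pr$points, sprintf("profile_points_%s_%s.tsv", cr, ax))
        tsv(pr$grid, sprintf("profile_curves_%s_%s.tsv", cr, ax))
        out[[paste(cr, ax, sep = "_")]] <- pr
      }
    }
    out
  })

  ## --- summary ---
  summary <- stage("report", {
    ord_sum <- lapply(ord, function(o)
      list(stress = o$stress, converged = o$converged,
           acceptable = o$acceptable,
           permanova = as.data.frame(o$permanova)))
    crit_sum <- lapply(config$criteria, function(cr) {
      row <- comparison[comparison$criterion == cr, ]
      list(criterion = cr,
           real_accuracy_mean = row$mean_real, real_accuracy_se = row$se_real,
           null_accuracy_mean = row$mean_null, null_accuracy_se = row$se_null,
           p_sidak = row$p_sidak,
           top_clades = utils::read.table(
             file.path(dir, sprintf("top_clades_%s.tsv", cr)),
             header = TRUE, sep = "\t", comment.char = "#"))
    })
    names(crit_sum) <- config$criteria
    s <- list(package = "cladeforest", version = ver, seed = seed,
              n_samples = nrow(sim$metadata), n_tips = config$n_tips,
              n_clades = ncol(feat$cm),
              criteria = crit_sum, ordination = ord_sum,
              effects = sim$effects)
    jsonlite::write_json(s, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    s
  })

  invisible(list(dir = dir, summary = summary, forests = forests,
                 comparison = comparison, ordination = ord,
                 profiles = profiles, matrix = feat$cm,
                 annotations = feat$ann, tree = sim$tree,
                 metadata = sim$metadata, effects = sim$effects))
}
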