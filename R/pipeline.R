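#' Read and validate a pipeline configuration
#'
#' The configuration is a plain YAML key-value file. Required keys:
#' `otu_table`, `metadata`, `out_dir`. Optional keys with defaults:
#' `taxonomy`, `tree`, `env` (paths; stages needing them are skipped when
#' absent), `rarefaction_depth` (1000), `seed` (1), `alpha` (0.05),
#' `family` ("within_class"), `dominance_threshold` (0.001),
#' `n_permutations` (9999), `rotation` ("oblimin").
#'
#' @param path Path to the YAML file, or a named list with the same keys.
#' @return Validated list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  for (key in c("otu_table", "metadata"))
    if (is.null(cfg[[key]]))
      stop("pipeline config must name '", key, "'", call. = FALSE)
  if (is.null(cfg$out_dir)) stop("pipeline config must name 'out_dir'",
                                 call. = FALSE)
  defaults <- list(rarefaction_depth = 1000, seed = 1, alpha = 0.05,
                   family = "within_class", dominance_threshold = 0.001,
                   n_permutations = 9999, rotation = "oblimin")
  for (key in names(defaults))
    if (is.null(cfg[[key]])) cfg[[key]] <- defaults[[key]]
  for (key in c("otu_table", "metadata", "taxonomy", "tree", "env"))
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("configured path does not exist: ", key, " = ", cfg[[key]],
           call. = FALSE)
  if (cfg$rarefaction_depth < 1 || cfg$alpha <= 0 || cfg$alpha >= 1 ||
      cfg$n_permutations < 1 || cfg$dominance_threshold < 0)
    stop("numeric pipeline parameters out of range", call. = FALSE)
  if (!cfg$family %in% c("within_class", "global"))
    stop("family must be 'within_class' or 'global'", call. = FALSE)
  if (!cfg$rotation %in% c("oblimin", "none"))
    stop("rotation must be 'oblimin' or 'none'", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

# internal: deterministic per-stage seeds split from the global seed
stage_seed <- function(seed, stage) {
  offsets <- c(rarefy = 11L, anosim = 23L, collector = 37L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Executes, in order: load/validate inputs; rarefaction (for the alpha-
#' and beta-diversity branches); per-sample alpha diversity and
#' upstream/downstream contrasts; Bray-Curtis (and, with a tree,
#' weighted-normalized UniFrac) distances with ANOSIM by reach
#' (reservoir samples excluded) and by campaign, for the whole community
#' and per class; origin and dominance categorization with per-class
#' reach-fraction summaries; per-class coherence partitions with subgroup
#' summaries, positive fractions and order-level composition; and, when an
#' environmental table is configured, rotated PCA plus OTU and class
#' correlations with the axes. Every stage writes a tab-separated table
#' into `out_dir`; a manifest lists the outputs with the configuration
#' hash and completeness flag.
#'
#' @param config A `pipeline_config`, a path to one, or a named list.
#' @return Invisibly, a list with the manifest data frame and the main
#'   in-memory results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    config <- read_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_table(df, path)
    written <<- c(written, name)
  }
  cfg_path <- file.path(config$out_dir, "pipeline_config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  finish <- function(complete) {
    manifest <- data.frame(file = written,
                           config_md5 = rep(cfg_hash, length(written)),
                           complete = rep(complete, length(written)),
                           stringsAsFactors = FALSE)
    write_table(manifest, file.path(config$out_dir, "manifest.tsv"))
    manifest
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      finish(FALSE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  results <- list()
  # stage 1: load and validate ---------------------------------------------
  stage("load", {
    table <- read_otu_table(config$otu_table)
    frames <- read_metadata(config$metadata)
    check_ids(colnames(table), frames$sample_id, "sample metadata")
    taxonomy <- if (!is.null(config$taxonomy)) read_taxonomy(config$taxonomy)
    tree <- if (!is.null(config$tree)) read_tree(config$tree)
    env <- if (!is.null(config$env)) read_env(config$env)
    message("loaded ", nrow(table), " OTUs x ", ncol(table), " samples")
    results$inputs <- list(table = table, frames = frames,
                            taxonomy = taxonomy, tree = tree, env = env)
  })
  inp <- results$inputs
  # stage 2: rarefaction ----------------------------------------------------
  stage("rarefy", {
    rar <- rarefy(inp$table, config$rarefaction_depth,
                  seed = stage_seed(config$seed, "rarefy"))
    dropped <- attr(rar, "dropped_samples")
    message("rarefied to ", config$rarefaction_depth, " sequences; dropped ",
            length(dropped), " sample(s)")
    emit(data.frame(sample_id = if (length(dropped)) dropped else character(),
                    stringsAsFactors = FALSE), "dropped_samples.tsv")
    results$rarefied <- rar
  })
  rar <- results$rarefied
  # stage 3: alpha diversity and reach contrasts ----------------------------
  stage("diversity", {
    alpha <- alpha_diversity(rar, tree = inp$tree)
    emit(alpha, "alpha_diversity.tsv")
    metrics <- c("n_sequences", "richness", "shannon",
                 if (!is.null(inp$tree)) "mpd")
    contrasts <- do.call(rbind, lapply(metrics, function(mm)
      reach_contrast(alpha, inp$frames, mm)))
    emit(contrasts, "reach_contrasts.tsv")
    results$contrasts <- contrasts
  })
  # stage 4: beta diversity and ANOSIM --------------------------------------
  stage("beta", {
    bc <- bray_curtis(rar)
    emit(data.frame(sample_id = rownames(bc), bc, check.names = FALSE),
         "bray_curtis.tsv")
    if (!is.null(inp$tree)) {
      uf <- weighted_normalized_unifrac(rar, inp$tree)
      emit(data.frame(sample_id = rownames(uf), uf, check.names = FALSE),
           "unifrac.tsv")
    }
    frames <- inp$frames
    aseed <- stage_seed(config$seed, "anosim")
    anosim_row <- function(d, ids, grouping, scope, what) {
      keep <- ids[grouping[ids] %in% names(table(grouping[ids]))[
        table(grouping[ids]) >= 2]]
      res <- anosim(d[keep, keep], grouping[keep],
                    n_permutations = config$n_permutations, seed = aseed)
      data.frame(scope = scope, grouping = what, R = res$statistic,
                 p_value = res$p_value,
                 n_permutations = res$n_permutations,
                 stringsAsFactors = FALSE)
    }
    reach <- stats::setNames(as.character(frames$reach), frames$sample_id)
    campaign <- stats::setNames(frames$campaign, frames$sample_id)
    updw <- rownames(bc)[reach[rownames(bc)] != "reservoir"]
    rows <- list(
      anosim_row(bc, updw, reach, "all", "reach"),
      anosim_row(bc, rownames(bc), campaign, "all", "campaign"))
    if (!is.null(inp$taxonomy)) {
      classes <- unique(stats::na.omit(inp$taxonomy$class))
      for (k in classes) {
        otus <- inp$taxonomy$otu_id[!is.na(inp$taxonomy$class) &
                                      inp$taxonomy$class == k]
        otus <- intersect(otus, rownames(rar))
        if (length(otus) < 2) next
        sub <- rar[otus, ]
        nz <- colnames(sub)[colSums(sub) > 0]
        if (length(nz) < 4) next
        d <- bray_curtis(sub[, nz])
        ok_updw <- intersect(updw, nz)
        rows[[length(rows) + 1]] <- tryCatch(
          rbind(anosim_row(d, ok_updw, reach, k, "reach"),
                anosim_row(d, nz, campaign, k, "campaign")),
          error = function(e) NULL)
      }
    }
    tab1 <- do.call(rbind, rows)
    emit(tab1, "anosim.tsv")
    results$anosim <- tab1
  })
  # stage 5: origin and dominance categorization ----------------------------
  stage("categorize", {
    origin <- assign_origin(inp$table, inp$frames)
    dominance <- assign_dominance(inp$table, inp$frames)
    emit(origin, "otu_origin.tsv")
    emit(dominance, "otu_dominance.tsv")
    if (!is.null(inp$taxonomy)) {
      emit(summarize_reach_fractions(inp$table, inp$frames, inp$taxonomy,
                                     origin, by = "origin"),
           "reach_fractions_origin.tsv")
      emit(summarize_reach_fractions(inp$table, inp$frames, inp$taxonomy,
                                     dominance, by = "dominance"),
           "reach_fractions_dominance.tsv")
    }
    results$origin <- origin
    results$dominance <- dominance
  })
  # stage 6: coherence partitions -------------------------------------------
  if (!is.null(inp$taxonomy)) stage("coherence", {
    parts <- partition_all_classes(inp$table, inp$taxonomy,
                                   alpha = config$alpha,
                                   family = config$family)
    dominant <- flag_dominant_otus(inp$table,
                                   threshold_fraction =
                                     config$dominance_threshold)
    records <- do.call(rbind, lapply(parts, function(p)
      cbind(class = p$class, p$records, stringsAsFactors = FALSE)))
    emit(records, "coherence_partition.tsv")
    summaries <- do.call(rbind, lapply(parts, function(p)
      subgroup_summary(p, inp$table, tree = inp$tree,
                       dominant_set = dominant)))
    emit(summaries, "subgroup_summary.tsv")
    fracs <- do.call(rbind, lapply(parts, function(p) {
      pf <- positive_fraction(p, inp$table)
      data.frame(class = p$class, otu_percent = pf$otu_percent,
                 sequence_percent = pf$sequence_percent,
                 stringsAsFactors = FALSE)
    }))
    emit(fracs, "positive_fractions.tsv")
    comp <- do.call(rbind, lapply(parts, function(p)
      subgroup_taxonomy(p, inp$table, inp$taxonomy)))
    emit(comp, "subgroup_taxonomy.tsv")
    results$partitions <- parts
    results$positive_fractions <- fracs
    results$subgroup_summary <- summaries
  })
  # stage 7: environmental response ------------------------------------------
  if (!is.null(inp$env)) stage("environment", {
    pca <- env_pca(inp$env, rotation = config$rotation)
    emit(data.frame(variable = rownames(pca$loadings), pca$loadings,
                    check.names = FALSE), "env_pca_loadings.tsv")
    emit(data.frame(sample_id = rownames(pca$scores), pca$scores,
                    check.names = FALSE), "env_pca_scores.tsv")
    emit(data.frame(component = c("PC1", "PC2"),
                    var_explained_unrotated = pca$var_explained,
                    var_explained_rotated = pca$var_explained_rotated,
                    total_var_explained = pca$total_var_explained,
                    inter_component_r = pca$phi[1, 2]),
         "env_pca_variance.tsv")
    # Axis correlations are reported unadjusted (the per-axis screening in
    # the source analyses shows raw p < 0.05); set adjust = "bonferroni"
    # upstream of this stage if a corrected screen is wanted.
    axis_otu <- correlate_with_axes(inp$table, pca, alpha = config$alpha)
    emit(axis_otu, "axis_correlations_otu.tsv")
    if (!is.null(inp$taxonomy)) {
      classes <- unique(stats::na.omit(inp$taxonomy$class))
      mat <- do.call(rbind, lapply(classes, function(k)
        class_abundance(inp$table, inp$taxonomy, focal = k)))
      rownames(mat) <- classes
      emit(correlate_with_axes(mat, pca, alpha = config$alpha),
           "axis_correlations_class.tsv")
    }
    results$env_pca <- pca
  })
  manifest <- finish(TRUE)
  message("pipeline complete: ", length(written), " tables in ",
          config$out_dir)
  invisible(c(list(manifest = manifest), results))
}
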