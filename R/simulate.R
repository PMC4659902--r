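#' Configuration for the synthetic river-metacommunity generator
#'
#' Defaults emulate the study design the package targets: 12 sites (6
#' upstream, 1 reservoir, 5 downstream) sampled in 3 campaigns; six
#' dominant classes with sequence shares 68 / 15 / 6 / 0.6 / 4 / 3 % and
#' Table-2-scale OTU richness, plus rare filler taxa carrying the
#' remaining share; per-sample depths drawn uniformly from 1000-6222;
#' within each class a planted fraction `coherent_fraction` of OTUs shares
#' the class's spatial response sign, `anti_fraction` responds with the
#' opposite sign, and the rest are null responders.
#'
#' @param sites_per_reach Named integer vector
#'   `c(upstream=, reservoir=, downstream=)`.
#' @param campaigns Character vector of campaign labels; the last one is
#'   treated as the winter campaign for the seasonal factor.
#' @param classes Data frame with columns `class`, `share`, `n_otus`,
#'   `trend` (+1 = more abundant downstream of the dam, -1 = upstream).
#' @param n_filler Number of rare filler OTUs carrying the residual share.
#' @param coherent_fraction,anti_fraction Planted per-class fractions of
#'   coherent and anti-responding OTUs (remainder null); each in \[0, 1\],
#'   sum at most 1.
#' @param beta_space Spatial (reservoir step) effect size on the log
#'   scale.
#' @param gamma_season Seasonal effect size on the log scale.
#' @param lognormal_sdlog sdlog of the within-class lognormal
#'   rank-abundance baseline.
#' @param jitter_cv Coefficient of variation of the per-OTU-per-sample
#'   lognormal jitter on expected abundance (overdispersion).
#' @param depth_range Integer vector `c(min, max)` of per-sample depths.
#' @param origin_probs Probabilities that an OTU's true origin is the
#'   upstream, reservoir, or downstream reach (it is absent upstream of
#'   its origin).
#' @param n_env Number of environmental variables (split between the
#'   seasonal and spatial factors).
#' @param env_noise_sd Standard deviation of environmental measurement
#'   noise.
#' @param class_monophyletic Make each class a clade in the simulated
#'   tree.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(sites_per_reach = c(upstream = 6, reservoir = 1,
                                           downstream = 5),
                       campaigns = c("Jul", "Sep", "Dec"),
                       classes = default_sim_classes(),
                       n_filler = 190,
                       coherent_fraction = 0.25,
                       anti_fraction = 0.25,
                       beta_space = 1.5,
                       gamma_season = 0.8,
                       lognormal_sdlog = 1.5,
                       jitter_cv = 0.3,
                       depth_range = c(1000, 6222),
                       origin_probs = c(upstream = 0.92, reservoir = 0.04,
                                        downstream = 0.04),
                       n_env = 9,
                       env_noise_sd = 0.3,
                       class_monophyletic = TRUE) {
  cfg <- list(sites_per_reach = sites_per_reach, campaigns = campaigns,
              classes = classes, n_filler = n_filler,
              coherent_fraction = coherent_fraction,
              anti_fraction = anti_fraction, beta_space = beta_space,
              gamma_season = gamma_season,
              lognormal_sdlog = lognormal_sdlog, jitter_cv = jitter_cv,
              depth_range = depth_range, origin_probs = origin_probs,
              n_env = n_env, env_noise_sd = env_noise_sd,
              class_monophyletic = class_monophyletic)
  if (sum(classes$share) > 1)
    stop("class shares sum to more than 1", call. = FALSE)
  if (coherent_fraction < 0 || coherent_fraction > 1 ||
      anti_fraction < 0 || coherent_fraction + anti_fraction > 1)
    stop("coherent_fraction and anti_fraction must lie in [0, 1] and sum ",
         "to at most 1", call. = FALSE)
  if (any(depth_range < 1) || depth_range[1] > depth_range[2])
    stop("depth_range must be increasing and at least 1", call. = FALSE)
  if (!all(abs(classes$trend) == 1))
    stop("class trend must be +1 or -1", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_sim_classes <- function() {
  data.frame(
    class = c("Actinobacteria", "Betaproteobacteria", "Alphaproteobacteria",
              "Gammaproteobacteria", "Flavobacteria", "Sphingobacteria"),
    share = c(0.68, 0.15, 0.06, 0.006, 0.04, 0.03),
    n_otus = c(390L, 150L, 80L, 45L, 65L, 36L),
    trend = c(1, -1, 1, -1, -1, -1),
    stringsAsFactors = FALSE)
}

# internal: phylum for each simulated class
sim_phylum <- function(class) {
  switch(class,
         Actinobacteria = "Actinobacteria",
         Betaproteobacteria = ,
         Alphaproteobacteria = ,
         Gammaproteobacteria = "Proteobacteria",
         Flavobacteria = ,
         Sphingobacteria = "Bacteroidetes",
         "OtherPhyla")
}

# internal: random bifurcating subtree with exponential branch lengths
sim_subtree <- function(tips, rate = 10) {
  if (length(tips) == 1) return(NULL)
  tr <- ape::rtree(length(tips), tip.label = tips,
                   br = function(n) stats::rexp(n, rate = rate))
  tr
}

#' Simulate a complete river-metacommunity input bundle
#'
#' Generates an OTU count table, taxonomy, rooted tree, sample metadata,
#' environmental table and the planted ground truth under the design in
#' [sim_config]. For OTU i the expected log abundance in sample s is
#' `log(base_i) + sigma_i * beta * (space(s) - 1/2) + g_i * gamma *
#' (season(s) - 1/2) + jitter`, where `space` steps from 0 to 1 at the
#' reservoir, `season` is the winter-campaign indicator, `sigma_i` is the
#' class trend for coherent OTUs, its negative for anti-responders and 0
#' for null responders (seasonal sign `g_i` follows the same pattern
#' around a per-class seasonal sign). Counts are drawn multinomially at a
#' per-sample depth drawn uniformly from `depth_range`, so column sums are
#' exact. Environmental variables are linear combinations of the same
#' space/season factors plus noise. The same seed gives a bit-identical
#' bundle.
#'
#' @param config A [sim_config].
#' @param seed Integer seed.
#' @return List of class `sim_bundle` with elements `table`
#'   ([otu_table]), `taxonomy`, `tree`, `frames`, `env`, `truth` (data
#'   frame: otu_id, class, label, sigma, season_sign, origin_true),
#'   `config`, `seed`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  # --- design -------------------------------------------------------------
  spr <- config$sites_per_reach
  site_ids <- c(sprintf("U%d", seq_len(spr[["upstream"]])),
                sprintf("R%d", seq_len(spr[["reservoir"]])),
                sprintf("D%d", seq_len(spr[["downstream"]])))
  site_reach <- rep(REACH_LEVELS, times = spr[REACH_LEVELS])
  frames <- do.call(rbind, lapply(config$campaigns, function(cp)
    data.frame(sample_id = paste(site_ids, cp, sep = "_"),
               site_id = site_ids, reach = site_reach,
               flow_order = seq_along(site_ids), campaign = cp,
               stringsAsFactors = FALSE)))
  frames <- validate_sample_frames(frames)
  nsamp <- nrow(frames)
  space <- as.numeric(frames$reach != "upstream")          # step at the dam
  winter <- config$campaigns[length(config$campaigns)]
  season <- as.numeric(frames$campaign == winter)
  # --- OTU inventory -------------------------------------------------------
  cls_df <- config$classes
  n_class_otus <- sum(cls_df$n_otus)
  n_total <- n_class_otus + config$n_filler
  otu_id <- sprintf("OTU%04d", seq_len(n_total))
  otu_class <- c(rep(cls_df$class, cls_df$n_otus),
                 rep("RareFiller", config$n_filler))
  # per-class planted labels, baselines and response signs
  label <- sigma <- gsign <- base <- numeric(0)
  season_sign_class <- stats::setNames(sample(c(-1, 1), nrow(cls_df),
                                              replace = TRUE), cls_df$class)
  for (ci in seq_len(nrow(cls_df))) {
    nk <- cls_df$n_otus[ci]
    n_coh <- round(config$coherent_fraction * nk)
    n_anti <- round(config$anti_fraction * nk)
    n_anti <- min(n_anti, nk - n_coh)
    lab <- sample(c(rep("coherent_with_class", n_coh),
                    rep("anti_responder", n_anti),
                    rep("null_responder", nk - n_coh - n_anti)))
    b <- stats::rlnorm(nk, meanlog = 0, sdlog = config$lognormal_sdlog)
    b <- b / sum(b) * cls_df$share[ci]
    sg <- ifelse(lab == "coherent_with_class", cls_df$trend[ci],
                 ifelse(lab == "anti_responder", -cls_df$trend[ci], 0))
    gs <- ifelse(lab == "coherent_with_class",
                 season_sign_class[[cls_df$class[ci]]],
                 ifelse(lab == "anti_responder",
                        -season_sign_class[[cls_df$class[ci]]], 0))
    label <- c(label, lab); sigma <- c(sigma, sg)
    gsign <- c(gsign, gs); base <- c(base, b)
  }
  if (config$n_filler > 0) {
    bf <- stats::rlnorm(config$n_filler, meanlog = 0, sdlog = 2)
    bf <- bf / sum(bf) * max(0, 1 - sum(cls_df$share))
    label <- c(label, rep("null_responder", config$n_filler))
    sigma <- c(sigma, rep(0, config$n_filler))
    gsign <- c(gsign, rep(0, config$n_filler))
    base <- c(base, bf)
  }
  origin_true <- sample(REACH_LEVELS, n_total, replace = TRUE,
                        prob = config$origin_probs[REACH_LEVELS])
  # --- expected abundances and multinomial counts --------------------------
  tau <- sqrt(log(1 + config$jitter_cv^2))
  loglam <- outer(log(base), rep(1, nsamp)) +
    outer(sigma * config$beta_space, space - 0.5) +
    outer(gsign * config$gamma_season, season - 0.5) +
    matrix(stats::rnorm(n_total * nsamp, 0, tau), n_total, nsamp)
  lam <- exp(loglam)
  reach_order <- as.integer(frames$reach)
  origin_order <- match(origin_true, REACH_LEVELS)
  lam[outer(origin_order, reach_order, ">")] <- 0   # absent upstream of origin
  depth_pool <- seq(config$depth_range[1], config$depth_range[2])
  depths <- depth_pool[sample.int(length(depth_pool), nsamp, replace = TRUE)]
  counts <- vapply(seq_len(nsamp), function(s)
    stats::rmultinom(1, depths[s], lam[, s])[, 1], integer(n_total))
  dimnames(counts) <- list(otu_id, frames$sample_id)
  tabl <- otu_table(counts)
  # --- taxonomy ------------------------------------------------------------
  n_orders <- pmax(2, pmin(4, ceiling(cls_df$n_otus / 30)))
  order_lab <- character(n_total)
  for (ci in seq_len(nrow(cls_df))) {
    rows <- which(otu_class == cls_df$class[ci])
    order_lab[rows] <- sample(paste0(cls_df$class[ci], "_order",
                                     seq_len(n_orders[ci])),
                              length(rows), replace = TRUE)
  }
  order_lab[otu_class == "RareFiller"] <- "RareFiller_order1"
  taxonomy <- data.frame(
    otu_id = otu_id, domain = "Bacteria",
    phylum = vapply(otu_class, sim_phylum, character(1), USE.NAMES = FALSE),
    class = otu_class, order = order_lab,
    family = NA_character_, genus = NA_character_,
    stringsAsFactors = FALSE)
  # --- tree ----------------------------------------------------------------
  tree <- sim_tree(otu_id, otu_class, config$class_monophyletic)
  # --- environmental table -------------------------------------------------
  env <- sim_env(frames, space, season, config$n_env, config$env_noise_sd)
  truth <- data.frame(otu_id = otu_id, class = otu_class, label = label,
                      sigma = sigma, season_sign = gsign,
                      beta_space = config$beta_space,
                      origin_true = origin_true, stringsAsFactors = FALSE)
  structure(list(table = tabl, taxonomy = taxonomy, tree = tree,
                 frames = frames, env = env, truth = truth,
                 config = config, seed = seed),
            class = "sim_bundle")
}

# internal: random bifurcating tree over all OTUs, optionally with each
# class monophyletic (class subtrees grafted onto a backbone)
sim_tree <- function(otu_id, otu_class, monophyletic) {
  if (!monophyletic || length(unique(otu_class)) == 1) {
    tr <- ape::rtree(length(otu_id), tip.label = sample(otu_id),
                     br = function(n) stats::rexp(n, rate = 10))
    return(validate_tree(tr))
  }
  groups <- split(otu_id, otu_class)
  backbone <- ape::rtree(length(groups), tip.label = names(groups),
                         br = function(n) stats::rexp(n, rate = 10))
  tr <- backbone
  for (g in names(groups)) {
    sub <- sim_subtree(groups[[g]])
    if (is.null(sub)) {                       # single-OTU group: rename tip
      tr$tip.label[tr$tip.label == g] <- groups[[g]]
      next
    }
    where <- which(tr$tip.label == g)
    tr <- ape::bind.tree(tr, sub, where = where)
  }
  validate_tree(tr)
}

# internal: environmental variables loading on the seasonal and spatial
# factors (first half seasonal, second half spatial) plus noise
sim_env <- function(frames, space, season, n_env, noise_sd) {
  seasonF <- 2 * (season - 0.5)
  spaceF <- 2 * (space - 0.5)
  names_pool <- c("temperature", "conductivity", "pH", "oxygen",
                  "srp", "doc", "din", "tss", "chla")
  vn <- if (n_env <= length(names_pool)) names_pool[seq_len(n_env)] else
    c(names_pool, sprintf("env%d", seq_len(n_env - length(names_pool))))
  n_seas <- ceiling(n_env / 2)
  env <- vapply(seq_len(n_env), function(v) {
    a <- if (v <= n_seas) sample(c(-1, 1), 1) else 0
    b <- if (v > n_seas) sample(c(-1, 1), 1) else 0
    a * seasonF + b * spaceF + stats::rnorm(nrow(frames), 0, noise_sd)
  }, numeric(nrow(frames)))
  dimnames(env) <- list(frames$sample_id, vn)
  attr(env, "factors") <- cbind(season = seasonF, space = spaceF)
  env
}

#' Write a simulated bundle to disk in the package's input formats
#'
#' Emits the five input files [read_otu_table], [read_taxonomy],
#' [read_tree], [read_metadata] and [read_env] can read back, plus
#' `ground_truth.tsv` and the serialized configuration.
#'
#' @param bundle A `sim_bundle` from [simulate_dataset].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    table = file.path(dir, "otu_table.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    tree = file.path(dir, "tree.nwk"),
    metadata = file.path(dir, "metadata.tsv"),
    env = file.path(dir, "environment.tsv"),
    truth = file.path(dir, "ground_truth.tsv"),
    config = file.path(dir, "sim_config.yaml"))
  write_otu_table(bundle$table, paths[["table"]])
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  lin <- apply(bundle$taxonomy[ranks], 1, function(z)
    paste(z[!is.na(z)], collapse = ";"))
  utils::write.table(data.frame(bundle$taxonomy$otu_id, lin),
                     paths[["taxonomy"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ape::write.tree(bundle$tree, paths[["tree"]])
  write_table(bundle$frames, paths[["metadata"]])
  env_df <- data.frame(sample_id = rownames(bundle$env), bundle$env,
                       check.names = FALSE)
  write_table(env_df, paths[["env"]])
  write_table(bundle$truth, paths[["truth"]])
  cfg <- bundle$config
  cfg$classes <- as.list(cfg$classes)
  yaml::write_yaml(c(unclass(cfg), seed = bundle$seed), paths[["config"]])
  invisible(paths)
}

#' Score recovery of the planted coherence structure
#'
#' Compares a coherence partition with the simulator's ground truth for
#' the same class: sensitivity (share of planted coherent OTUs given the
#' positive verdict), specificity (share of anti/null responders not given
#' the positive verdict), and the absolute error between the recovered
#' positive-OTU fraction (among testable OTUs) and the planted coherent
#' fraction among that class's OTUs.
#'
#' @param partition A `coherence_partition`.
#' @param truth Ground-truth data frame from [simulate_dataset].
#' @return Named numeric vector `sensitivity`, `specificity`,
#'   `fraction_error`.
#' @export
score_recovery <- function(partition, truth) {
  rec <- partition$records
  tr <- truth[truth$class == partition$class, ]
  shared <- intersect(rec$otu_id, tr$otu_id)
  if (length(shared) == 0)
    stop("partition and ground truth share no OTUs for class ",
         partition$class, call. = FALSE)
  rec <- rec[match(shared, rec$otu_id), ]
  tr <- tr[match(shared, tr$otu_id), ]
  coh <- tr$label == "coherent_with_class"
  pos <- rec$verdict == "positive"
  testable <- rec$verdict != "untestable"
  sens <- if (any(coh)) mean(pos[coh]) else NA_real_
  spec <- if (any(!coh)) mean(!pos[!coh]) else NA_real_
  f_planted <- mean(coh)
  f_recovered <- if (any(testable)) sum(pos) / sum(testable) else NA_real_
  c(sensitivity = sens, specificity = spec,
    fraction_error = abs(f_recovered - f_planted))
}
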