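# Shared in-code fixtures: tiny hand-checkable tables, trees and designs.

# 3 OTUs x 2 samples with known counts
tiny_table <- function() {
  otu_table(matrix(c(1L, 0L, 2L, 5L, 0L, 3L), nrow = 3, byrow = TRUE,
                   dimnames = list(paste0("OTU", 1:3), c("s1", "s2"))))
}

# 12-site, 3-campaign design mirroring the study layout (6 up / 1 res / 5 down)
study_frames <- function(campaigns = c("Jul", "Sep", "Dec")) {
  sites <- c(paste0("U", 1:6), "R1", paste0("D", 1:5))
  reach <- rep(c("upstream", "reservoir", "downstream"), c(6, 1, 5))
  validate_sample_frames(do.call(rbind, lapply(campaigns, function(cp)
    data.frame(sample_id = paste(sites, cp, sep = "_"), site_id = sites,
               reach = reach, flow_order = seq_along(sites), campaign = cp,
               stringsAsFactors = FALSE))))
}

# minimal single-campaign frames for named samples split by reach
frames_for <- function(up, rs = character(), dw = character()) {
  ids <- c(up, rs, dw)
  validate_sample_frames(data.frame(
    sample_id = ids, site_id = ids,
    reach = rep(c("upstream", "reservoir", "downstream"),
                c(length(up), length(rs), length(dw))),
    flow_order = seq_along(ids), campaign = "Jul",
    stringsAsFactors = FALSE))
}

# star tree: k tips, all branch lengths 1, patristic distance 2 everywhere
star_tree <- function(k = 3) {
  tr <- ape::stree(k, type = "star")
  tr$tip.label <- paste0("OTU", seq_len(k))
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

# caterpillar tree ((A:1,B:1):1,C:2):0 with pairwise distances 2, 4, 4
caterpillar_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,C:2):0;")
}

# small simulated bundle for I/O round-trips and joins
small_bundle <- function(seed = 1) {
  simulate_dataset(sim_config(
    classes = data.frame(class = c("Betaproteobacteria", "Actinobacteria"),
                         share = c(0.5, 0.35), n_otus = c(30L, 20L),
                         trend = c(-1, 1), stringsAsFactors = FALSE),
    n_filler = 10, depth_range = c(1000, 2000)), seed = seed)
}

# the recovery-experiment generator configuration: one focal class carrying
# half the community, flat-ish rank-abundance, strong reservoir step, no
# anti-responders (the planted coherent group is the class signal)
recovery_config <- function(f, anti = 0) {
  sim_config(
    classes = data.frame(class = "Betaproteobacteria", share = 0.5,
                         n_otus = 40L, trend = -1, stringsAsFactors = FALSE),
    n_filler = 40, coherent_fraction = f, anti_fraction = anti,
    beta_space = 3, lognormal_sdlog = 1, depth_range = c(2000, 2000))
}

# drop 4 winter samples so n = 32, as in the study design
drop_winter <- function(table, n_drop = 4) {
  dec <- grep("_Dec$", colnames(table), value = TRUE)
  table[, setdiff(colnames(table), head(dec, n_drop))]
}

# all permutations of 1:n as rows (n! x n), for exhaustive enumeration
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- combinat_perms(n - 1)
  out <- do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
  unname(out)
}

# construct a coherence_partition directly from verdict counts and pooled
# per-OTU sequence counts (for worked-example arithmetic on printed inputs)
partition_from_counts <- function(class_label, n_positive, n_nonsig,
                                  seq_positive, seq_nonsig) {
  n <- n_positive + n_nonsig
  otus <- sprintf("%s_OTU%03d", class_label, seq_len(n))
  verdict <- rep(c("positive", "nonsignificant"), c(n_positive, n_nonsig))
  rec <- data.frame(otu_id = otus, pearson_r = NA_real_, p_raw = NA_real_,
                    p_adjusted = NA_real_,
                    verdict = factor(verdict,
                                     levels = c("positive", "negative",
                                                "nonsignificant",
                                                "untestable")),
                    stringsAsFactors = FALSE)
  part <- structure(list(class = class_label, records = rec,
                         family_size = n, alpha = 0.05, n_samples = NA,
                         self_inclusion = TRUE),
                    class = "coherence_partition")
  # one-sample table whose pooled counts split the printed sequence totals
  # evenly within each subgroup (remainder on the first OTU)
  split_counts <- function(total, k) {
    if (k == 0) return(integer(0))
    base <- rep(total %/% k, k)
    base[1] <- base[1] + total %% k
    base
  }
  counts <- matrix(c(split_counts(seq_positive, n_positive),
                     split_counts(seq_nonsig, n_nonsig)), ncol = 1,
                   dimnames = list(otus, "pooled"))
  list(partition = part, table = otu_table(counts))
}
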