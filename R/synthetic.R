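#' Synthetic study specification
#'
#' Collects the knobs of the synthetic-data generators. The defaults emulate
#' the study design the pipeline targets: a label-free FFPE proteomics layer
#' of ~4958 protein groups over 10 poor / 9 good responders with
#' intensity-dependent missingness and a small fraction of bovine-contaminant
#' and reverse-decoy rows, and a 549-gene targeted immuno-oncology panel over
#' 11 poor / 14 good responders with 15 housekeeping genes of which one is
#' generated at low signal. Planted group effects default to a 1.5 log2-unit
#' shift with 0.5 log2 within-group standard deviation.
#'
#' @param n_features number of features (protein groups or panel genes).
#' @param n_good,n_poor samples per responder group (each >= 2).
#' @param effect_log2 planted group-mean difference, log2 scale.
#' @param within_group_sd within-group noise sd, log2 scale.
#' @param frac_affected fraction of (non-contaminant, non-housekeeping)
#'   features carrying a planted effect.
#' @param frac_bovine,frac_reverse contaminant/decoy row fractions
#'   (proteomics only).
#' @param missing_rate overall expected fraction of missing cells
#'   (proteomics only; dropout is logistic in log2 intensity, so low-intensity
#'   cells are preferentially missing).
#' @param n_housekeeping housekeeping genes (panel only, >= 2).
#' @param baseline_mean,baseline_sd log2-scale mean/sd of feature baselines.
#' @param seed integer seed; fixed seed means fully reproducible output.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_features = 4958, n_good = 9, n_poor = 10,
                           effect_log2 = 1.5, within_group_sd = 0.5,
                           frac_affected = 0.045, frac_bovine = 0.01,
                           frac_reverse = 0.01, missing_rate = 0.10,
                           n_housekeeping = 15, baseline_mean = 20,
                           baseline_sd = 2.5, seed = 1) {
  fracs <- c(frac_affected, frac_bovine, frac_reverse, missing_rate)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  if (n_features < 1 || n_good < 2 || n_poor < 2) {
    abort("need n_features >= 1 and >= 2 samples per group")
  }
  structure(
    list(n_features = as.integer(n_features), n_good = as.integer(n_good),
         n_poor = as.integer(n_poor), effect_log2 = effect_log2,
         within_group_sd = within_group_sd, frac_affected = frac_affected,
         frac_bovine = frac_bovine, frac_reverse = frac_reverse,
         missing_rate = missing_rate, n_housekeeping = as.integer(n_housekeeping),
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @rdname synthetic_spec
#' @export
panel_spec <- function(n_features = 549, n_good = 14, n_poor = 11,
                       effect_log2 = 1.5, within_group_sd = 0.5,
                       frac_affected = 0.08, n_housekeeping = 15,
                       baseline_mean = 17, baseline_sd = 2, seed = 1) {
  synthetic_spec(n_features = n_features, n_good = n_good, n_poor = n_poor,
                 effect_log2 = effect_log2, within_group_sd = within_group_sd,
                 frac_affected = frac_affected, frac_bovine = 0,
                 frac_reverse = 0, missing_rate = 0,
                 n_housekeeping = n_housekeeping,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 seed = seed)
}

synthetic_design <- function(spec, prefix) {
  ids <- sprintf("%s%02d", prefix, seq_len(spec$n_poor + spec$n_good))
  group_design(ids, c(rep("poor", spec$n_poor), rep("good", spec$n_good)))
}

# shared core: log2 matrix with planted effects; returns values + truth
plant_effects <- function(spec, feature_id, eligible, design) {
  n <- length(feature_id)
  mu <- stats::rnorm(n, spec$baseline_mean, spec$baseline_sd)
  n_aff <- round(spec$frac_affected * n)
  aff_idx <- sort(sample(which(eligible), min(n_aff, sum(eligible))))
  dir <- rep(0L, n)
  dir[aff_idx] <- sample(c(-1L, 1L), length(aff_idx), replace = TRUE)
  good <- design$group == "good"
  x <- matrix(stats::rnorm(n * nrow(design), 0, spec$within_group_sd),
              n, nrow(design), dimnames = list(feature_id, design$sample_id))
  x <- x + mu
  x[, good] <- x[, good] + dir * spec$effect_log2
  truth <- tibble(
    feature_id = feature_id,
    affected = dir != 0L,
    direction = c("up_in_poor", "none", "up_in_good")[dir + 2L],
    effect_log2 = dir * spec$effect_log2
  )
  list(log2 = x, truth = truth)
}

# logistic intensity-dependent dropout calibrated so the mean missing
# probability equals `rate`; scale of 1 log2 unit for the dropout slope
apply_dropout <- function(x, rate, slope = 1) {
  if (rate <= 0) return(x)
  xs <- as.vector(x)
  f <- function(m0) mean(stats::plogis((m0 - xs) / slope)) - rate
  lo <- min(xs) - 30; hi <- max(xs) + 30
  m0 <- stats::uniroot(f, c(lo, hi))$root
  p <- stats::plogis((m0 - x) / slope)
  x[stats::runif(length(x)) < p] <- NA_real_
  x
}

#' Generate a synthetic label-free proteomics matrix
#'
#' Feature baselines are drawn log-normal (normal on the log2 scale); affected
#' features shift the good-responder group mean by `effect_log2` in a random
#' direction; bovine and reverse rows are flagged and never carry a planted
#' effect; missingness is logistic in log2 intensity so dropout concentrates
#' at low intensities. The returned truth table records which features were
#' affected and in which direction.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `matrix` (raw-scale [abundance_tbl()]), `truth` (tibble:
#'   `feature_id`, `affected`, `direction`, `effect_log2`) and `design`
#'   (a [group_design()]).
#' @export
generate_proteomics <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_features
  fid <- sprintf("PROT%05d", seq_len(n))
  design <- synthetic_design(spec, "PS")
  n_bov <- round(spec$frac_bovine * n)
  n_rev <- round(spec$frac_reverse * n)
  contam <- sample(n, n_bov + n_rev)
  bovine <- seq_len(n) %in% contam[seq_len(n_bov)]
  reverse <- seq_len(n) %in% contam[n_bov + seq_len(n_rev)]
  planted <- plant_effects(spec, fid, eligible = !bovine & !reverse, design)
  x <- apply_dropout(planted$log2, spec$missing_rate)
  flags <- tibble(feature_id = fid, bovine = bovine, reverse = reverse)
  mat <- abundance_tbl(2^x, flags = flags, scale = "raw",
                       zero_as_missing = FALSE)
  truth <- mutate(planted$truth, bovine = bovine, reverse = reverse)
  list(matrix = mat, truth = truth, design = design)
}

#' Generate a synthetic targeted mRNA panel
#'
#' Emulates a housekeeping-normalized targeted expression panel: no missing
#' values, `n_housekeeping` genes with no group effect and tight dispersion
#' (log2 sd 0.1), of which exactly one is generated at low signal (8 log2
#' units below the housekeeping baseline) to exercise the low-signal
#' exclusion rule. Signals are continuous positive abundances, since the
#' analysis consumes normalized log2 signals rather than integer counts.
#'
#' @param spec a [synthetic_spec()]; see [panel_spec()] for panel defaults.
#' @return list with `matrix`, `truth` (extra `housekeeping` column) and
#'   `design`, as in [generate_proteomics()].
#' @export
generate_mrna_panel <- function(spec = panel_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_housekeeping < 2) abort("need n_housekeeping >= 2")
  if (spec$n_housekeeping >= spec$n_features) {
    abort("n_housekeeping must be smaller than n_features")
  }
  set.seed(spec$seed)
  n <- spec$n_features
  n_hk <- spec$n_housekeeping
  fid <- c(sprintf("HK%02d", seq_len(n_hk)),
           sprintf("GENE%04d", seq_len(n - n_hk)))
  hk <- seq_len(n) <= n_hk
  design <- synthetic_design(spec, "MS")
  planted <- plant_effects(spec, fid, eligible = !hk, design)
  x <- planted$log2
  # housekeeping rows: common high baseline, tight dispersion, no effect
  hk_mu <- spec$baseline_mean + 2
  x[hk, ] <- hk_mu + matrix(stats::rnorm(n_hk * nrow(design), 0, 0.1),
                            n_hk, nrow(design))
  low_hk <- sample(n_hk, 1)
  x[low_hk, ] <- x[low_hk, ] - 8
  flags <- tibble(feature_id = fid, housekeeping = hk)
  mat <- abundance_tbl(2^x, flags = flags, scale = "raw",
                       zero_as_missing = FALSE)
  truth <- mutate(planted$truth, housekeeping = hk,
                  low_signal_hk = seq_len(n) == low_hk)
  list(matrix = mat, truth = truth, design = design)
}

#' Generate gene sets with one planted enriched set
#'
#' Builds a GMT-style collection: one `PLANTED_RESPONSE_SET` drawing
#' `enrichment_ratio` of its members from truly affected features (the rest
#' from unaffected ones), plus `n_decoy_sets` decoys sampled uniformly from
#' the universe. A fraction of out-of-universe symbols is mixed into every
#' set to exercise universe pruning.
#'
#' @param truth truth tibble from a generator (needs `feature_id`, `affected`).
#' @param universe observed gene symbols.
#' @param n_decoy_sets number of decoy sets.
#' @param set_size members per set.
#' @param enrichment_ratio fraction of the planted set drawn from affected
#'   features.
#' @param n_out_of_universe out-of-universe symbols appended per set.
#' @param seed integer seed.
#' @return a [gene_set_tbl()].
#' @export
generate_gene_sets <- function(truth, universe, n_decoy_sets = 50,
                               set_size = 25, enrichment_ratio = 0.6,
                               n_out_of_universe = 2, seed = 1) {
  if (length(universe) == 0) abort("universe must be nonempty")
  set.seed(seed)
  affected <- intersect(truth$feature_id[truth$affected], universe)
  unaffected <- setdiff(universe, affected)
  n_aff <- min(round(enrichment_ratio * set_size), length(affected))
  planted <- c(sample(affected, n_aff),
               sample(unaffected, min(set_size - n_aff, length(unaffected))))
  out_syms <- function(i) sprintf("OUTSIDE%03d_%d", seq_len(n_out_of_universe), i)
  nm <- c("PLANTED_RESPONSE_SET", sprintf("DECOY_SET_%03d", seq_len(n_decoy_sets)))
  sets <- c(
    list(c(planted, out_syms(0))),
    lapply(seq_len(n_decoy_sets), function(i) {
      c(sample(universe, min(set_size, length(universe))), out_syms(i))
    })
  )
  gene_set_tbl(nm, c("planted enriched set", rep("uniform decoy set", n_decoy_sets)),
               sets)
}

#' Generate a synthetic interaction network
#'
#' A preferential-attachment background graph plus a designated subset of the
#' seed symbols wired into a connected cluster (a path among themselves, each
#' member also attached to the background); the remaining seeds are attached
#' to background nodes only, so they have no edges to any other seed.
#'
#' @param seeds seed node symbols.
#' @param n_background background node count.
#' @param m_edges_per_node preferential-attachment edges per new node.
#' @param frac_cluster fraction of seeds wired into the connected cluster.
#' @param seed integer seed.
#' @return an [interaction_tbl()] with attributes `cluster_seeds` and
#'   `isolated_seeds`.
#' @export
generate_network <- function(seeds, n_background = 100, m_edges_per_node = 2,
                             frac_cluster = 0.6, seed = 1) {
  if (n_background < 2 || m_edges_per_node < 1) abort("counts must be positive")
  seeds <- unique(seeds)
  set.seed(seed)
  g <- igraph::sample_pa(n_background, m = m_edges_per_node, directed = FALSE)
  bg <- sprintf("BG%04d", seq_len(n_background))
  el <- igraph::as_edgelist(g, names = FALSE)
  from <- bg[el[, 1]]; to <- bg[el[, 2]]
  n_clust <- max(2L, ceiling(frac_cluster * length(seeds)))
  n_clust <- min(n_clust, length(seeds))
  cluster_seeds <- seeds[seq_len(n_clust)]
  isolated_seeds <- setdiff(seeds, cluster_seeds)
  # densely interconnected cluster: each seed linked to up to 3 predecessors,
  # emulating the tight functional clusters of curated interaction databases
  if (n_clust >= 2) {
    for (lag in 1:3) {
      if (n_clust > lag) {
        from <- c(from, cluster_seeds[seq_len(n_clust - lag)])
        to <- c(to, cluster_seeds[seq_len(n_clust - lag) + lag])
      }
    }
  }
  anchors <- sample(bg, length(seeds), replace = TRUE)
  from <- c(from, seeds)
  to <- c(to, anchors)
  net <- interaction_tbl(from, to, rep("pp", length(from)))
  attr(net, "cluster_seeds") <- cluster_seeds
  attr(net, "isolated_seeds") <- isolated_seeds
  net
}
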