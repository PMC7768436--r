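pipeline_defaults <- function() {
  list(
    mode = "synthetic",
    seed = 1L,
    outdir = NULL,
    synthetic = list(
      n_features = 4958L, n_good = 9L, n_poor = 10L,
      effect_log2 = 1.5, within_group_sd = 0.5, frac_affected = 0.045,
      frac_bovine = 0.01, frac_reverse = 0.01, missing_rate = 0.10,
      n_housekeeping = 15L,
      panel_n_features = 549L, panel_n_good = 14L, panel_n_poor = 11L,
      panel_frac_affected = 0.08,
      n_decoy_sets = 50L, set_size = 25L, enrichment_ratio = 0.6,
      n_background = 150L, m_edges_per_node = 2L
    ),
    inputs = list(
      proteomics = NULL, proteomics_design = NULL,
      panel = NULL, panel_design = NULL,
      gmt = NULL, edges = NULL
    ),
    thresholds = list(fold = 1.5, alpha = 0.05, hellinger = 0.25,
                      min_per_group = 3L),
    enrichment = list(universe = "combined", min_pruned_size = 3L),
    network = list(min_connections = 3L, extras = character())
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a nested list; fills defaults, range-checks
#' every threshold, and rejects unknown keys with a nearest-key suggestion.
#' Either synthetic mode or a full set of input paths must be configured.
#'
#' @param config YAML file path or named list (possibly partial).
#' @return a complete, validated config list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  defaults <- pipeline_defaults()
  merged <- merge_config(config, defaults, path = "")
  th <- merged$thresholds
  # constructor range-checks fold/alpha/hellinger/min_per_group
  filter_thresholds(th$fold, th$alpha, th$hellinger, th$min_per_group)
  if (!merged$mode %in% c("synthetic", "files")) {
    abort("mode must be 'synthetic' or 'files'")
  }
  if (!merged$enrichment$universe %in% c("proteomics", "mrna", "combined")) {
    abort("enrichment universe must be 'proteomics', 'mrna' or 'combined'")
  }
  if (merged$enrichment$min_pruned_size < 1) abort("min_pruned_size must be >= 1")
  if (merged$network$min_connections < 0) abort("min_connections must be >= 0")
  if (merged$mode == "files") {
    need <- c("proteomics", "proteomics_design", "panel", "panel_design",
              "gmt", "edges")
    absent <- need[vapply(merged$inputs[need], is.null, TRUE)]
    if (length(absent) > 0) {
      abort(sprintf("mode 'files' needs input paths: %s",
                    paste(absent, collapse = ", ")))
    }
  }
  merged$seed <- as.integer(merged$seed)
  structure(merged, class = "pipeline_config")
}

merge_config <- function(user, defaults, path) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    d <- utils::adist(unknown[1], names(defaults))
    hint <- if (min(d) <= 3) sprintf("; did you mean '%s'?",
                                     names(defaults)[which.min(d)]) else ""
    abort(sprintf("unknown config key '%s%s'%s", path, unknown[1], hint))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]])) abort(sprintf("config key '%s%s' must be a mapping", path, k))
      defaults[[k]] <- merge_config(user[[k]], defaults[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

read_design_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(df))) {
    abort(sprintf("'%s': design needs sample_id and group columns", path))
  }
  group_design(df$sample_id, df$group)
}

#' Run the full responder-comparison pipeline
#'
#' Executes, per omics layer, normalize -> differential -> direction split,
#' then pruned Fisher enrichment on the combined candidates and seed-node
#' direct-interaction network extraction. In synthetic mode all inputs are
#' generated from the config's seed; in files mode they are read from the
#' configured paths. When `outdir` is set, every stage's table is written as
#' a deterministic TSV so identical runs produce bytewise-identical trees.
#'
#' @param config a [validate_config()] result, raw list, or YAML path.
#' @return object of class `pipeline_run`: manifest plus per-stage results
#'   (`differential`, `enrichment`, `subnetwork`, `normalized`, ...).
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  th <- filter_thresholds(config$thresholds$fold, config$thresholds$alpha,
                          config$thresholds$hellinger,
                          config$thresholds$min_per_group)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    inform(sprintf("[%s] done in %.2fs", name,
                   as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  syn <- config$synthetic
  truth <- NULL
  if (config$mode == "synthetic") {
    prot_spec <- synthetic_spec(
      n_features = syn$n_features, n_good = syn$n_good, n_poor = syn$n_poor,
      effect_log2 = syn$effect_log2, within_group_sd = syn$within_group_sd,
      frac_affected = syn$frac_affected, frac_bovine = syn$frac_bovine,
      frac_reverse = syn$frac_reverse, missing_rate = syn$missing_rate,
      seed = config$seed
    )
    pan_spec <- panel_spec(
      n_features = syn$panel_n_features, n_good = syn$panel_n_good,
      n_poor = syn$panel_n_poor, effect_log2 = syn$effect_log2,
      within_group_sd = syn$within_group_sd,
      frac_affected = syn$panel_frac_affected,
      n_housekeeping = syn$n_housekeeping, seed = config$seed + 1L
    )
    prot <- stage("simulate-proteomics", generate_proteomics(prot_spec))
    pan <- stage("simulate-panel", generate_mrna_panel(pan_spec))
    prot_mat <- prot$matrix; prot_design <- prot$design
    pan_mat <- pan$matrix; pan_design <- pan$design
    truth <- dplyr::bind_rows(
      mutate(prot$truth, layer = "proteomics"),
      mutate(pan$truth, layer = "mrna")
    )
  } else {
    prot_mat <- stage("read-proteomics",
                      read_abundance_matrix(config$inputs$proteomics))
    prot_design <- read_design_tsv(config$inputs$proteomics_design)
    pan_mat <- stage("read-panel", read_abundance_matrix(config$inputs$panel))
    pan_design <- read_design_tsv(config$inputs$panel_design)
  }

  # proteomics layer: contaminant exclusion, IRON vs median sample
  excl <- stage("exclude-contaminants", exclude_contaminants(prot_mat))
  prot_norm <- stage("normalize-proteomics", normalize_proteomics(excl$matrix))
  prot_diff <- stage("differential-proteomics",
                     two_group_table(prot_norm$matrix, prot_design, th))
  prot_split <- split_directions(prot_diff)

  # panel layer: housekeeping geometric mean + scale factor
  hk_sel <- stage("select-housekeeping", select_housekeeping(pan_mat))
  pan_norm <- stage("normalize-panel",
                    normalize_housekeeping(pan_mat,
                                           hk_sel$feature_id[hk_sel$retained]))
  pan_diff <- stage("differential-panel",
                    two_group_table(pan_norm$matrix, pan_design, th))
  pan_split <- split_directions(pan_diff)

  prot_universe <- excl$matrix$feature_id
  mrna_universe <- pan_mat$feature_id
  universe_tbl <- combine_universes(prot_universe, mrna_universe)
  universe <- switch(config$enrichment$universe,
                     proteomics = prot_universe,
                     mrna = mrna_universe,
                     combined = universe_tbl$gene)

  prot_cand <- prot_diff$feature_id[prot_diff$passes]
  pan_cand <- pan_diff$feature_id[pan_diff$passes]
  candidates <- union(prot_cand, pan_cand)

  if (config$mode == "synthetic") {
    sets <- stage("simulate-gene-sets",
                  generate_gene_sets(truth, universe_tbl$gene,
                                     n_decoy_sets = syn$n_decoy_sets,
                                     set_size = syn$set_size,
                                     enrichment_ratio = syn$enrichment_ratio,
                                     seed = config$seed + 2L))
    net <- stage("simulate-network",
                 generate_network(if (length(candidates) > 0) candidates
                                  else universe_tbl$gene[seq_len(5)],
                                  n_background = syn$n_background,
                                  m_edges_per_node = syn$m_edges_per_node,
                                  seed = config$seed + 3L))
  } else {
    sets <- stage("read-gmt", read_gmt(config$inputs$gmt))
    net <- stage("read-edges", read_edge_list(config$inputs$edges))
  }

  pruned <- stage("prune-sets",
                  prune_sets(sets, universe, config$enrichment$min_pruned_size))
  enr <- if (length(candidates) > 0) {
    stage("enrichment", fisher_enrichment(intersect(candidates, universe), pruned))
  } else {
    warn("no candidates passed the filter; skipping enrichment")
    structure(tibble(set_name = character(), k = integer(),
                     n_candidates = integer(), m_set = integer(),
                     N_universe = integer(), p_raw = double(),
                     p_adj = double(), overlap_genes = list()),
              class = c("enrichment_tbl", class(tibble())))
  }

  seeds <- merge_seed_sets(prot_cand, pan_cand)
  sub <- if (nrow(seeds) > 0) {
    s0 <- stage("network", direct_subnetwork(seeds, net))
    s1 <- filter_min_connections(s0, config$network$min_connections)
    if (length(config$network$extras) > 0) {
      s1 <- augment_with_nodes(s1, config$network$extras, net)
    }
    s1
  } else {
    new_subnetwork(tibble(node = character(), origin = character(),
                          flag = character()),
                   interaction_tbl())
  }

  manifest <- tibble(
    proteomics_features_in = nrow(prot_mat),
    excluded_contaminants = nrow(excl$excluded),
    proteomics_tested = sum(prot_diff$reason == ""),
    proteomics_low_n = sum(prot_diff$reason == "low_n"),
    proteomics_candidates = length(prot_cand),
    proteomics_up_in_good = nrow(prot_split$up_in_good),
    proteomics_up_in_poor = nrow(prot_split$up_in_poor),
    panel_features_in = nrow(pan_mat),
    housekeeping_retained = sum(hk_sel$retained),
    housekeeping_excluded = sum(!hk_sel$retained),
    scale_factor = pan_norm$scale_factor$factor,
    mrna_candidates = length(pan_cand),
    mrna_up_in_good = nrow(pan_split$up_in_good),
    mrna_up_in_poor = nrow(pan_split$up_in_poor),
    total_candidates = length(prot_cand) + length(pan_cand),
    sets_tested = nrow(enr),
    subnetwork_members = nrow(sub$members),
    subnetwork_edges = nrow(sub$edges),
    seed = config$seed,
    version = as.character(utils::packageVersion("responderomics"))
  )
  stopifnot(manifest$total_candidates ==
              manifest$proteomics_up_in_good + manifest$proteomics_up_in_poor +
              manifest$mrna_up_in_good + manifest$mrna_up_in_poor)

  run <- structure(
    list(manifest = manifest, config = config,
         differential = list(proteomics = prot_diff, mrna = pan_diff),
         splits = list(proteomics = prot_split, mrna = pan_split),
         normalized = list(proteomics = prot_norm, panel = pan_norm),
         hk_selection = hk_sel, universe = universe_tbl,
         enrichment = enr, network = net, subnetwork = sub,
         truth = truth),
    class = "pipeline_run"
  )
  if (!is.null(config$outdir)) write_pipeline_outputs(run, config$outdir)
  run
}

write_pipeline_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  diff_cols <- function(d) select(as_tibble(d), -dplyr::any_of("reason"))
  write_records(diff_cols(run$differential$proteomics),
                p("differential_proteomics.tsv"),
                sort_by = c("t_p", "feature_id"))
  write_records(diff_cols(run$differential$mrna), p("differential_mrna.tsv"),
                sort_by = c("t_p", "feature_id"))
  write_records(as_tibble(run$enrichment), p("enrichment.tsv"),
                sort_by = c("p_raw", "set_name"))
  write_records(run$subnetwork$members, p("network_nodes.tsv"),
                sort_by = "node")
  write_records(run$subnetwork$edges, p("network_edges.tsv"),
                sort_by = c("from", "to"))
  write_records(as_tibble(run$hk_selection), p("housekeeping_selection.tsv"),
                sort_by = "feature_id")
  write_abundance_matrix(run$normalized$proteomics$matrix,
                         p("normalized_proteomics.tsv"))
  write_abundance_matrix(run$normalized$panel$matrix,
                         p("normalized_panel.tsv"))
  if (!is.null(run$truth)) {
    write_records(run$truth, p("truth.tsv"), sort_by = c("layer", "feature_id"))
  }
  write_records(run$manifest, p("manifest.tsv"))
  invisible(outdir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    paste0("responder-comparison run (seed %d)\n",
           "  proteomics: %d features in, %d contaminants excluded, %d candidates (%d up/%d down)\n",
           "  panel: %d genes, %d/%d housekeeping retained, scale factor %g, %d candidates\n",
           "  combined: %d candidates, %d gene sets tested, subnetwork %d nodes / %d edges\n"),
    m$seed, m$proteomics_features_in, m$excluded_contaminants,
    m$proteomics_candidates, m$proteomics_up_in_good, m$proteomics_up_in_poor,
    m$panel_features_in, m$housekeeping_retained,
    m$housekeeping_retained + m$housekeeping_excluded, m$scale_factor,
    m$mrna_candidates, m$total_candidates, m$sets_tested,
    m$subnetwork_members, m$subnetwork_edges))
  invisible(x)
}
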