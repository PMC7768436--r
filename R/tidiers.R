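#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy / summarize a differential table
#'
#' `tidy()` returns the per-feature record tibble; `glance()` returns a
#' one-row summary with feature, candidate and direction counts plus the
#' thresholds used.
#'
#' @param x a `differential_tbl` from [two_group_table()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.differential_tbl <- function(x, ...) as_tibble(x)

#' @rdname tidy.differential_tbl
#' @export
glance.differential_tbl <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble(
    n_features = nrow(x),
    n_tested = sum(x$reason == ""),
    n_low_n = sum(x$reason == "low_n"),
    n_pass = sum(x$passes),
    n_up_in_good = sum(x$direction == "up_in_good"),
    n_up_in_poor = sum(x$direction == "up_in_poor"),
    fold_threshold = th$fold_threshold,
    alpha = th$alpha,
    h_threshold = th$h_threshold
  )
}

#' Tidy / summarize an enrichment table
#'
#' `tidy()` returns per-set records with overlaps flattened to a
#' comma-separated string; `glance()` counts tested and significant sets.
#'
#' @param x an `enrichment_tbl` from [fisher_enrichment()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.enrichment_tbl <- function(x, ...) {
  mutate(as_tibble(x),
         overlap_genes = vapply(.data$overlap_genes, paste, "", collapse = ","))
}

#' @rdname tidy.enrichment_tbl
#' @export
glance.enrichment_tbl <- function(x, ...) {
  tibble(
    n_sets = nrow(x),
    n_sig_raw_05 = sum(x$p_raw < 0.05),
    n_sig_adj_05 = sum(x$p_adj < 0.05),
    top_set = if (nrow(x) > 0) x$set_name[1] else NA_character_,
    N_universe = if (nrow(x) > 0) x$N_universe[1] else NA_integer_
  )
}

#' Tidy / summarize a subnetwork
#'
#' `tidy()` returns the member table; `glance()` one row of size and
#' component counts.
#'
#' @param x a `subnetwork` from [direct_subnetwork()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.subnetwork <- function(x, ...) as_tibble(x$members)

#' @rdname tidy.subnetwork
#' @export
glance.subnetwork <- function(x, ...) {
  tibble(
    n_members = nrow(x$members),
    n_edges = nrow(x$edges),
    n_components = length(unique(stats::na.omit(x$members$component))),
    max_degree = if (nrow(x$members) > 0) max(x$members$degree) else 0L
  )
}

#' Tidy / summarize a pipeline run
#'
#' `tidy()` returns the combined per-feature differential table across both
#' omics layers with a `layer` column; `glance()` returns the one-row run
#' manifest.
#'
#' @param x a `pipeline_run` from [run_pipeline()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.pipeline_run <- function(x, ...) {
  dplyr::bind_rows(
    mutate(as_tibble(x$differential$proteomics), layer = "proteomics"),
    mutate(as_tibble(x$differential$mrna), layer = "mrna")
  )
}

#' @rdname tidy.pipeline_run
#' @export
glance.pipeline_run <- function(x, ...) x$manifest
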