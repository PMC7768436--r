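#' Prune gene sets to the observed universe
#'
#' Intersects every set with the observed-gene universe and drops sets whose
#' pruned size falls below `min_pruned_size` (default 3). Pruning restricts
#' both the sets and the enrichment background to genes the experiment could
#' actually observe, correcting the composition bias of a targeted panel.
#'
#' @param collection a [gene_set_tbl()].
#' @param universe nonempty character vector of observed symbols.
#' @param min_pruned_size minimum post-pruning set size (default 3).
#' @return a pruned [gene_set_tbl()] with its `universe` attribute set.
#' @export
prune_sets <- function(collection, universe, min_pruned_size = 3) {
  if (length(universe) == 0) abort("universe must be nonempty")
  universe <- unique(trimws(universe))
  pruned <- lapply(collection$genes, intersect, y = universe)
  keep <- lengths(pruned) >= min_pruned_size
  if (any(!keep)) {
    inform(sprintf("dropping %d set(s) with pruned size < %d",
                   sum(!keep), min_pruned_size))
  }
  gene_set_tbl(collection$set_name[keep], collection$description[keep],
               pruned[keep], universe = universe)
}

#' Fisher's exact over-representation of candidate genes in gene sets
#'
#' One-sided (upper-tail) hypergeometric test per set: the probability of an
#' overlap at least as large as observed, given the pruned set size `m_set`,
#' the candidate count `n_candidates`, and the pruned universe size
#' `N_universe` as the background. Benjamini-Hochberg adjustment is applied
#' across all tested sets; rows are sorted by raw p ascending, then set name.
#'
#' @param candidates candidate gene symbols (out-of-universe symbols are
#'   dropped with a warning).
#' @param collection a pruned [gene_set_tbl()] (see [prune_sets()]).
#' @return tibble of class `enrichment_tbl`: `set_name`, `k`, `n_candidates`,
#'   `m_set`, `N_universe`, `p_raw`, `p_adj`, `overlap_genes` (list-column).
#' @export
fisher_enrichment <- function(candidates, collection) {
  universe <- set_universe(collection)
  if (is.null(universe)) abort("collection is not pruned; run prune_sets() first")
  candidates <- unique(trimws(candidates))
  outside <- setdiff(candidates, universe)
  if (length(outside) > 0) {
    warn(sprintf("dropping %d candidate(s) outside the universe", length(outside)))
    candidates <- setdiff(candidates, outside)
  }
  if (length(candidates) == 0) {
    warn("no candidates within the universe; empty enrichment")
  }
  N <- length(universe)
  n <- length(candidates)
  k <- vapply(collection$genes, function(g) length(intersect(g, candidates)), 0L)
  m <- lengths(collection$genes)
  # upper tail P(X >= k) for X ~ Hypergeometric(N, m, n)
  p_raw <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
  out <- tibble(
    set_name = collection$set_name,
    k = as.integer(k), n_candidates = n, m_set = as.integer(m),
    N_universe = N,
    p_raw = p_raw,
    p_adj = stats::p.adjust(p_raw, method = "BH"),
    overlap_genes = lapply(collection$genes, intersect, y = candidates)
  )
  out <- out[order_c(out$p_raw, out$set_name), ]
  structure(out, class = c("enrichment_tbl", class(tibble())))
}

#' Combine observed-gene universes across omics layers
#'
#' Set union of the proteomics and mRNA observed-gene universes, with each
#' symbol's provenance retained.
#'
#' @param proteomics_universe,mrna_universe nonempty character vectors.
#' @return tibble: `gene`, `provenance` (`"proteomics"`, `"mrna"`, `"both"`).
#' @export
combine_universes <- function(proteomics_universe, mrna_universe) {
  if (length(proteomics_universe) == 0 || length(mrna_universe) == 0) {
    abort("both universes must be nonempty")
  }
  p <- unique(trimws(proteomics_universe))
  m <- unique(trimws(mrna_universe))
  genes <- sort(union(p, m), method = "radix")
  provenance <- ifelse(genes %in% p & genes %in% m, "both",
                       ifelse(genes %in% p, "proteomics", "mrna"))
  tibble(gene = genes, provenance = provenance)
}
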