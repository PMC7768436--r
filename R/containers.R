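#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange left_join bind_rows across
#' @importFrom stats median sd quantile approx runmed setNames p.adjust phyper
#' @importFrom utils head
NULL

FLAG_COLUMNS <- c("housekeeping", "bovine", "reverse")

#' Build an abundance table
#'
#' An `abundance_tbl` is the package's feature-by-sample container: a tibble
#' with one row per feature, a `feature_id` column, logical flag columns
#' (`housekeeping`, `bovine`, `reverse`) and one numeric column per sample.
#' `NA` marks a missing (unobserved) measurement; on the raw scale all present
#' values must be strictly positive, and raw zeros are treated as missing by
#' default because in label-free intensity data a zero means "not observed"
#' rather than a measured abundance of zero.
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). `NA` = missing.
#' @param flags optional data frame/tibble with `feature_id` plus any of the
#'   logical columns `housekeeping`, `bovine`, `reverse`. Absent flags default
#'   to `FALSE`.
#' @param scale `"raw"` (positive intensities) or `"log2"`.
#' @param zero_as_missing on the raw scale, convert 0 values to `NA`
#'   (default `TRUE`).
#' @return a tibble of class `abundance_tbl`.
#' @export
abundance_tbl <- function(values, flags = NULL, scale = c("raw", "log2"),
                          zero_as_missing = TRUE) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    abort("`values` must have feature ids as rownames and sample ids as colnames")
  }
  check_unique(fid, "feature id")
  check_unique(sid, "sample id")
  if (scale == "raw" && zero_as_missing) {
    values[!is.na(values) & values == 0] <- NA_real_
  }
  if (scale == "raw") {
    bad <- which(!is.na(values) & values <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      abort(sprintf(
        "non-positive raw value %g at feature '%s', sample '%s'",
        values[bad[1, 1], bad[1, 2]], fid[bad[1, 1]], sid[bad[1, 2]]
      ))
    }
  }
  out <- tibble(feature_id = fid)
  for (fl in FLAG_COLUMNS) out[[fl]] <- rep(FALSE, length(fid))
  if (!is.null(flags)) {
    flags <- as_tibble(flags)
    if (!"feature_id" %in% names(flags)) abort("`flags` needs a feature_id column")
    keep <- intersect(FLAG_COLUMNS, names(flags))
    idx <- match(out$feature_id, flags$feature_id)
    for (fl in keep) {
      v <- as.logical(flags[[fl]])[idx]
      out[[fl]] <- ifelse(is.na(v), FALSE, v)
    }
  }
  vals <- as_tibble(as.data.frame(values, check.names = FALSE))
  out <- dplyr::bind_cols(out, vals)
  new_abundance_tbl(out, sample_ids = sid, scale = scale)
}

new_abundance_tbl <- function(df, sample_ids, scale) {
  structure(
    as_tibble(df),
    sample_ids = sample_ids,
    scale = scale,
    class = c("abundance_tbl", class(as_tibble(df)))
  )
}

#' Sample ids / scale / value matrix of an abundance table
#'
#' Accessors for the `abundance_tbl` container. `abundance_values()` returns
#' the plain feature-by-sample numeric matrix (rownames = feature ids).
#'
#' @param x an `abundance_tbl`.
#' @return character vector, character scalar, or numeric matrix respectively.
#' @export
sample_ids <- function(x) attr(x, "sample_ids")

#' @rdname sample_ids
#' @export
abundance_scale <- function(x) attr(x, "scale")

#' @rdname sample_ids
#' @export
abundance_values <- function(x) {
  m <- as.matrix(x[, sample_ids(x), drop = FALSE])
  rownames(m) <- x$feature_id
  m
}

# rebuild an abundance_tbl from a value matrix, carrying flags from `template`
rebuild_abundance <- function(values, template, scale) {
  flags <- template[, c("feature_id", FLAG_COLUMNS)]
  abundance_tbl(values, flags = flags, scale = scale,
                zero_as_missing = FALSE)
}

check_unique <- function(x, what) {
  d <- unique(x[duplicated(x)])
  if (length(d) > 0) {
    abort(sprintf("duplicate %ss: %s", what,
                  paste(utils::head(d, 5), collapse = ", ")))
  }
  invisible(x)
}

#' Two-group sample design
#'
#' Assigns every sample to one of exactly two responder groups. Group roles
#' are fixed: `"good"` is the ratio numerator and `"poor"` the denominator,
#' so positive log2 ratios read "higher in good responders".
#'
#' @param sample_id character vector of sample ids.
#' @param group character vector of `"good"`/`"poor"` labels, same length.
#' @return a tibble of class `group_design` with columns `sample_id`, `group`.
#' @export
group_design <- function(sample_id, group) {
  if (length(sample_id) != length(group)) abort("lengths differ")
  check_unique(sample_id, "sample id")
  bad <- setdiff(unique(group), c("good", "poor"))
  if (length(bad) > 0) {
    abort(sprintf("group labels must be 'good' or 'poor'; got: %s",
                  paste(bad, collapse = ", ")))
  }
  tab <- table(factor(group, levels = c("good", "poor")))
  if (any(tab < 2)) abort("each group needs at least 2 samples")
  structure(tibble(sample_id = sample_id, group = group),
            class = c("group_design", class(tibble())))
}

design_samples <- function(design, g) design$sample_id[design$group == g]

check_design <- function(x, design) {
  missing <- setdiff(design$sample_id, sample_ids(x))
  if (length(missing) > 0) {
    abort(sprintf("design references samples absent from the matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  extra <- setdiff(sample_ids(x), design$sample_id)
  if (length(extra) > 0) {
    abort(sprintf("samples without a group assignment: %s",
                  paste(extra, collapse = ", ")))
  }
  invisible(design)
}

#' Gene-set collection
#'
#' A tibble with one row per gene set: `set_name`, `description` and a
#' list-column `genes` of unique member symbols. The observed-gene universe
#' used for enrichment pruning is carried in the `universe` attribute once
#' [prune_sets()] has run. Symbols are matched case-sensitively after
#' whitespace trimming; no alias resolution is attempted.
#'
#' @param set_name character vector of unique set names.
#' @param description character vector of descriptions.
#' @param genes list of character vectors of member symbols.
#' @param universe optional character vector of observed symbols.
#' @return a tibble of class `gene_set_tbl`.
#' @export
gene_set_tbl <- function(set_name = character(), description = character(),
                         genes = list(), universe = NULL) {
  check_unique(set_name, "set name")
  genes <- lapply(genes, function(g) unique(trimws(g)))
  if (any(lengths(genes) == 0) && length(genes) > 0) {
    abort("gene sets must be nonempty")
  }
  structure(
    tibble(set_name = set_name, description = description, genes = genes),
    universe = universe,
    class = c("gene_set_tbl", class(tibble()))
  )
}

#' @rdname gene_set_tbl
#' @param x a `gene_set_tbl`.
#' @export
set_universe <- function(x) attr(x, "universe")

#' Molecular interaction network
#'
#' An undirected edge table: one row per canonical edge with columns `from`,
#' `to` (symbols, `from <= to` lexicographically in the C locale) and
#' `relation` (optional label, `""` when absent). Self-loops are disallowed;
#' duplicate edges are collapsed keeping the first relation label seen.
#'
#' @param from,to character vectors of endpoint symbols.
#' @param relation optional character vector of relation labels.
#' @return a tibble of class `interaction_tbl`.
#' @export
interaction_tbl <- function(from = character(), to = character(),
                            relation = rep("", length(from))) {
  from <- trimws(from); to <- trimws(to)
  if (any(from == "") || any(to == "")) abort("blank node symbol")
  self <- from == to
  if (any(self)) {
    warn(sprintf("dropping %d self-loop(s)", sum(self)))
    from <- from[!self]; to <- to[!self]; relation <- relation[!self]
  }
  lo <- pmin_chr(from, to)
  hi <- pmax_chr(from, to)
  df <- tibble(from = lo, to = hi, relation = relation)
  df <- df[!duplicated(df[, c("from", "to")]), ]
  df <- df[order_c(df$from, df$to), ]
  structure(df, class = c("interaction_tbl", class(tibble())))
}

# locale-independent string comparison helpers (C collation via comparison of
# raw bytes through `<` after forcing the C locale ordering with `rank` on
# encoded strings is fragile; base `<` on character uses the active collation,
# so sort keys go through order_c below)
pmin_chr <- function(a, b) ifelse(compare_c(a, b) <= 0, a, b)
pmax_chr <- function(a, b) ifelse(compare_c(a, b) <= 0, b, a)
compare_c <- function(a, b) {
  out <- integer(length(a))
  lt <- vapply(seq_along(a), function(i) {
    o <- order(c(a[i], b[i]), method = "radix")
    if (a[i] == b[i]) 0L else if (o[1] == 1L) -1L else 1L
  }, integer(1))
  lt
}

# order by multiple keys with radix (C-locale, platform independent)
order_c <- function(...) order(..., method = "radix")

net_nodes <- function(net) sort(unique(c(net$from, net$to)), method = "radix")

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    as.data.frame(net[, c("from", "to", "relation")]),
    directed = FALSE,
    vertices = net_nodes(net)
  )
}
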