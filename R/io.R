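#' Read a feature-by-sample abundance matrix from TSV
#'
#' Expects tab-separated text with a header row: first column is the feature
#' id, optional annotation columns (by default any of `housekeeping`,
#' `bovine`, `reverse`, holding 0/1 or TRUE/FALSE), then one numeric column
#' per sample. Empty cells and the `na` sentinel become missing values.
#' Raw-scale zeros become missing unless `zero_as_missing = FALSE`.
#'
#' @param path file path.
#' @param flag_columns names of annotation columns to read as feature flags.
#' @param scale `"raw"` or `"log2"`.
#' @param na sentinel string treated as missing (default `"NA"`).
#' @param zero_as_missing treat raw 0 as missing (default `TRUE`).
#' @return an [abundance_tbl()].
#' @export
read_abundance_matrix <- function(path, flag_columns = FLAG_COLUMNS,
                                  scale = c("raw", "log2"), na = "NA",
                                  zero_as_missing = TRUE) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, check.names = FALSE, na.strings = na,
                          colClasses = "character", blank.lines.skip = FALSE)
  if (ncol(df) < 2) abort(sprintf("'%s': need a feature id column plus data", path))
  fid <- trimws(df[[1]])
  check_unique(fid, "feature id")
  flag_cols <- intersect(flag_columns, names(df)[-1])
  sample_cols <- setdiff(names(df)[-1], flag_cols)
  check_unique(sample_cols, "sample id")
  vals <- matrix(NA_real_, nrow(df), length(sample_cols),
                 dimnames = list(fid, sample_cols))
  for (j in seq_along(sample_cols)) {
    raw <- df[[sample_cols[j]]]
    raw[!is.na(raw) & trimws(raw) == ""] <- NA
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad) > 0) {
      abort(sprintf("'%s': non-numeric value '%s' at feature '%s', sample '%s'",
                    path, raw[bad[1]], fid[bad[1]], sample_cols[j]))
    }
    if (scale == "raw") {
      neg <- which(!is.na(num) & num < 0)
      if (length(neg) > 0) {
        abort(sprintf("'%s': negative value %s at feature '%s', sample '%s'",
                      path, raw[neg[1]], fid[neg[1]], sample_cols[j]))
      }
    }
    vals[, j] <- num
  }
  flags <- NULL
  if (length(flag_cols) > 0) {
    flags <- tibble(feature_id = fid)
    for (fl in flag_cols) {
      v <- trimws(df[[fl]])
      flags[[fl]] <- v %in% c("1", "TRUE", "true", "T")
    }
  }
  abundance_tbl(vals, flags = flags, scale = scale,
                zero_as_missing = zero_as_missing)
}

#' Write an abundance table to TSV
#'
#' Inverse of [read_abundance_matrix()]: writes feature id, the flag columns
#' (as 0/1), then sample columns. Missing values are written as `NA`. Values
#' use the same fixed formatting as [write_records()], so identical tables
#' produce identical bytes.
#'
#' @param x an [abundance_tbl()].
#' @param path output file path.
#' @export
write_abundance_matrix <- function(x, path) {
  m <- abundance_values(x)
  out <- data.frame(feature_id = x$feature_id, check.names = FALSE)
  for (fl in FLAG_COLUMNS) out[[fl]] <- as.integer(x[[fl]])
  for (s in colnames(m)) out[[s]] <- format_num(m[, s])
  write_tsv_bytes(out, path)
}

#' Read gene sets in GMT format
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a line are deduplicated; duplicate set names and lines with
#' fewer than three fields are errors naming the line.
#'
#' @param path GMT file path.
#' @return a [gene_set_tbl()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(gene_set_tbl())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    abort(sprintf("'%s' line %d: GMT lines need name, description and >=1 gene",
                  path, which(nf < 3)[1]))
  }
  nm <- trimws(vapply(parts, `[[`, "", 1))
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0) {
    abort(sprintf("'%s': duplicate set name '%s' (line %d)",
                  path, dup[1], which(nm == dup[1])[2]))
  }
  desc <- vapply(parts, `[[`, "", 2)
  genes <- lapply(parts, function(p) {
    g <- trimws(p[-(1:2)])
    unique(g[nzchar(g)])
  })
  empty <- which(lengths(genes) == 0)
  if (length(empty) > 0) {
    abort(sprintf("'%s' line %d: gene set '%s' has no genes",
                  path, empty[1], nm[empty[1]]))
  }
  gene_set_tbl(nm, desc, genes)
}

#' Write gene sets in GMT format
#' @param x a [gene_set_tbl()].
#' @param path output file path.
#' @export
write_gmt <- function(x, path) {
  lines <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(x$set_name[i], x$description[i], x$genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read a SIF-like interaction edge list
#'
#' Accepts lines of either `nodeA<TAB>relation<TAB>nodeB` or `nodeA<TAB>nodeB`
#' (empty relation). Edges are undirected: reversed duplicates collapse to one
#' canonical edge, and self-loops are dropped with a warning.
#'
#' @param path file path.
#' @return an [interaction_tbl()].
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) return(interaction_tbl())
  # sentinel keeps trailing empty fields (strsplit drops them otherwise)
  parts <- lapply(strsplit(paste0(lines, "\x01"), "\t", fixed = TRUE),
                  function(p) { p[length(p)] <- sub("\x01$", "", p[length(p)]); p })
  nf <- lengths(parts)
  if (any(!nf %in% c(2L, 3L))) {
    abort(sprintf("'%s' line %d: expected 2 or 3 tab-separated fields",
                  path, lineno[which(!nf %in% c(2L, 3L))[1]]))
  }
  a <- trimws(vapply(parts, `[[`, "", 1))
  b <- trimws(vapply(parts, function(p) p[[length(p)]], ""))
  rel <- vapply(parts, function(p) if (length(p) == 3L) trimws(p[[2]]) else "", "")
  blank <- which(a == "" | b == "")
  if (length(blank) > 0) {
    abort(sprintf("'%s' line %d: blank node symbol", path, lineno[blank[1]]))
  }
  interaction_tbl(a, b, rel)
}

#' Write an interaction network as a 3-column SIF-like edge list
#' @param x an [interaction_tbl()].
#' @param path output file path.
#' @export
write_edge_list <- function(x, path) {
  writeLines(paste(x$from, x$relation, x$to, sep = "\t"), path, sep = "\n")
  invisible(path)
}

#' Write a result table deterministically
#'
#' Writes any of the pipeline's result tibbles as TSV with a documented,
#' reproducible layout: columns in their current order, rows sorted by
#' `sort_by` (ties broken left to right, C-locale radix order), p-value-like
#' columns (`p`, `p_raw`, `p_adj`, `t_p`, names ending in `_p`) in fixed
#' 6-significant-digit scientific notation and other numeric columns in fixed
#' `%.6g`, so identical inputs yield bytewise-identical files.
#'
#' @param records a data frame of results.
#' @param path output file path.
#' @param sort_by character vector of column names to sort rows by.
#' @return the path, invisibly.
#' @export
write_records <- function(records, path, sort_by = NULL) {
  records <- as_tibble(records)
  if (!is.null(sort_by) && nrow(records) > 0) {
    missing <- setdiff(sort_by, names(records))
    if (length(missing) > 0) abort(sprintf("unknown sort column: %s", missing[1]))
    records <- records[do.call(order_c, unname(records[sort_by])), ]
  }
  out <- as.data.frame(records, check.names = FALSE)
  p_like <- grepl("(^p$|^p_raw$|^p_adj$|_p$)", names(out))
  for (j in seq_along(out)) {
    if (is.list(out[[j]])) {
      out[[j]] <- vapply(out[[j]], function(v) paste(v, collapse = ","), "")
    } else if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- if (p_like[j]) format_p(out[[j]]) else format_num(out[[j]])
    } else if (is.logical(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "NA", ifelse(out[[j]], "TRUE", "FALSE"))
    }
  }
  write_tsv_bytes(out, path)
}

format_p <- function(x) ifelse(is.na(x), "NA", sprintf("%.5e", x))
format_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", x))

write_tsv_bytes <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df) > 0) {
    rows <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}
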