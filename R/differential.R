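#' Composite-filter thresholds
#'
#' The candidate filter is the conjunction of three conditions on each
#' feature's two-group summary: `|log2_ratio| >= log2(fold_threshold)`,
#' Welch t-test `p < alpha`, and Hellinger distance `> h_threshold`, with a
#' minimum number of present values per group. Defaults are the published
#' cutoffs: 1.5-fold, 0.05, 0.25, and 3 present values per group.
#'
#' @param fold_threshold fold-change cutoff, > 1 (default 1.5).
#' @param alpha t-test significance level (default 0.05).
#' @param h_threshold Hellinger-distance cutoff in (0,1) (default 0.25).
#' @param min_per_group minimum present values per group (default 3).
#' @param sd_floor absolute floor on per-group sd in the Hellinger estimator;
#'   `NULL` (default) floors at 1e-6 times the matrix's median absolute log2
#'   signal at computation time.
#' @return a list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(fold_threshold = 1.5, alpha = 0.05,
                              h_threshold = 0.25, min_per_group = 3,
                              sd_floor = NULL) {
  if (fold_threshold <= 1) abort("fold_threshold must be > 1")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  if (h_threshold <= 0 || h_threshold >= 1) abort("h_threshold must lie in (0, 1)")
  if (min_per_group < 2) abort("min_per_group must be >= 2")
  structure(list(fold_threshold = fold_threshold, alpha = alpha,
                 h_threshold = h_threshold,
                 min_per_group = as.integer(min_per_group),
                 sd_floor = sd_floor),
            class = "filter_thresholds")
}

#' Drop bovine-contaminant and reverse-decoy rows
#'
#' @param x an [abundance_tbl()] with feature flags.
#' @return list with `matrix` (filtered) and `excluded` (tibble: `feature_id`,
#'   `reason`).
#' @export
exclude_contaminants <- function(x) {
  drop <- x$bovine | x$reverse
  excluded <- tibble(
    feature_id = x$feature_id[drop],
    reason = ifelse(x$bovine[drop], "bovine", "reverse")
  )
  kept <- x[!drop, , drop = FALSE]
  if (nrow(kept) == 0) warn("all rows flagged as contaminants; empty matrix")
  inform(sprintf("excluded %d contaminant row(s) (%d bovine, %d reverse)",
                 sum(drop), sum(x$bovine), sum(x$reverse)))
  kept <- new_abundance_tbl(kept, sample_ids = sample_ids(x),
                            scale = abundance_scale(x))
  list(matrix = kept, excluded = excluded)
}

#' Welch two-sample t-test
#'
#' Unequal-variance (Welch-Satterthwaite) two-sided t-test via
#' [stats::t.test()], with explicit handling of degenerate variances: when
#' both samples are constant, equal means give `t = 0, p = 1` and different
#' means give `p = 0` with a `degenerate` flag.
#'
#' @param a,b numeric vectors, >= 2 values each.
#' @return tibble: `t_stat`, `t_df`, `t_p`, `degenerate`.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) abort("each sample needs >= 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(t_stat = 0, t_df = length(a) + length(b) - 2,
                    t_p = 1, degenerate = FALSE))
    }
    return(tibble(t_stat = sign(mean(a) - mean(b)) * Inf,
                  t_df = length(a) + length(b) - 2, t_p = 0,
                  degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  tibble(t_stat = unname(tt$statistic), t_df = unname(tt$parameter),
         t_p = tt$p.value, degenerate = FALSE)
}

#' Hellinger distance between two normal approximations
#'
#' Closed form for two univariate normals:
#' `H = sqrt(1 - sqrt(2*s1*s2/(s1^2+s2^2)) * exp(-(mu1-mu2)^2 / (4*(s1^2+s2^2))))`,
#' with each sd floored at `sd_floor` before use. This is the package's
#' estimator of group separation: each group's log2 signals are summarized by
#' their sample mean and sd and treated as a normal distribution. With few
#' observations per group this is an interpretation, not a nonparametric
#' distance.
#'
#' @param mu1,sd1,mu2,sd2 group means and sds (vectorized).
#' @param sd_floor positive floor applied to both sds (default 1e-6).
#' @return Hellinger distance in `[0, 1]`.
#' @export
hellinger_normal <- function(mu1, sd1, mu2, sd2, sd_floor = 1e-6) {
  s1 <- pmax(sd1, sd_floor); s2 <- pmax(sd2, sd_floor)
  v <- s1^2 + s2^2
  bc <- sqrt(2 * s1 * s2 / v) * exp(-(mu1 - mu2)^2 / (4 * v))
  sqrt(pmax(0, 1 - bc))
}

#' Per-feature two-group differential table
#'
#' For every feature of a normalized log2 matrix, computes present-value
#' counts, group means and sds, the log2 ratio (good − poor), Welch t
#' statistics, the normal-approximation Hellinger distance, and the composite
#' pass/fail with direction. Features with fewer than `min_per_group` present
#' values in either group are reported with `passes = FALSE` and reason
#' `"low_n"`. Rows are sorted by `|log2_ratio|` descending, then feature id.
#'
#' @param x log2-scale [abundance_tbl()].
#' @param design a [group_design()].
#' @param thresholds a [filter_thresholds()].
#' @return tibble of class `differential_tbl` with one row per feature.
#' @export
two_group_table <- function(x, design, thresholds = filter_thresholds()) {
  if (abundance_scale(x) != "log2") abort("expected a log2-scale matrix")
  check_design(x, design)
  m <- abundance_values(x)
  good <- m[, design_samples(design, "good"), drop = FALSE]
  poor <- m[, design_samples(design, "poor"), drop = FALSE]
  sd_floor <- thresholds$sd_floor %||%
    (1e-6 * stats::median(abs(m), na.rm = TRUE))
  row_stats <- function(mm) {
    list(n = unname(rowSums(!is.na(mm))),
         mean = unname(rowMeans(mm, na.rm = TRUE)),
         sd = unname(apply(mm, 1, stats::sd, na.rm = TRUE)))
  }
  g <- row_stats(good); p <- row_stats(poor)
  n_feat <- nrow(m)
  t_stat <- t_df <- t_p <- rep(NA_real_, n_feat)
  enough <- g$n >= pmax(2L, thresholds$min_per_group) &
    p$n >= pmax(2L, thresholds$min_per_group)
  for (i in which(enough)) {
    w <- welch_t(good[i, ], poor[i, ])
    t_stat[i] <- w$t_stat; t_df[i] <- w$t_df; t_p[i] <- w$t_p
  }
  log2_ratio <- g$mean - p$mean
  hell <- ifelse(enough,
                 hellinger_normal(g$mean, g$sd, p$mean, p$sd, sd_floor),
                 NA_real_)
  passes <- enough &
    !is.na(t_p) &
    abs(log2_ratio) >= log2(thresholds$fold_threshold) &
    t_p < thresholds$alpha &
    hell > thresholds$h_threshold
  direction <- ifelse(passes,
                      ifelse(log2_ratio > 0, "up_in_good", "up_in_poor"),
                      "none")
  reason <- ifelse(enough, "", "low_n")
  out <- tibble(
    feature_id = rownames(m),
    n_good = as.integer(g$n), n_poor = as.integer(p$n),
    mean_good = g$mean, mean_poor = p$mean,
    log2_ratio = log2_ratio,
    sd_good = g$sd, sd_poor = p$sd,
    t_stat = t_stat, t_df = t_df, t_p = t_p,
    hellinger = hell,
    passes = passes, direction = direction, reason = reason
  )
  out <- out[order_c(-abs(out$log2_ratio), out$feature_id), ]
  structure(out, thresholds = thresholds,
            class = c("differential_tbl", class(tibble())))
}

#' Split passing features by direction
#'
#' @param records a `differential_tbl` from [two_group_table()].
#' @return list with tibbles `up_in_good` and `up_in_poor` (passing records
#'   partitioned by the sign of the log2 ratio).
#' @export
split_directions <- function(records) {
  up_good <- filter(as_tibble(records), .data$passes, .data$direction == "up_in_good")
  up_poor <- filter(as_tibble(records), .data$passes, .data$direction == "up_in_poor")
  inform(sprintf("%d candidates: %d up in good, %d up in poor",
                 nrow(up_good) + nrow(up_poor), nrow(up_good), nrow(up_poor)))
  list(up_in_good = up_good, up_in_poor = up_poor)
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact enumeration (via [stats::wilcox.test()] with `exact = TRUE`) when
#' the combined sample size is at most 20 and the data are tie-free;
#' otherwise the normal approximation with tie correction and continuity
#' correction. Used for group comparisons of externally supplied per-sample
#' quantities such as immune-cell fractions.
#'
#' @param a,b numeric vectors, nonempty.
#' @return two-sided p-value.
#' @export
mann_whitney_exact <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) abort("samples must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 20) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  min(1, wt$p.value)
}
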