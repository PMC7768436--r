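#' Geometric mean
#'
#' `exp(mean(log(x)))` for strictly positive values; the housekeeping
#' normalization denominator.
#'
#' @param x nonempty numeric vector, all values > 0.
#' @return positive scalar.
#' @export
geometric_mean <- function(x) {
  if (length(x) == 0) abort("geometric_mean of empty vector")
  if (any(is.na(x)) || any(x <= 0)) {
    abort("geometric_mean requires positive, non-missing values")
  }
  exp(mean(log(x)))
}

#' Select housekeeping genes, excluding low-signal ones
#'
#' A housekeeping gene is excluded when its median raw signal across samples
#' falls below `low_signal_quantile` times the matrix-wide typical signal
#' (the median over samples of each sample's median signal). This
#' operationalizes the practice of dropping a housekeeping gene whose signal
#' is too low to be a reliable normalization denominator.
#'
#' @param x raw-scale [abundance_tbl()] with >= 2 housekeeping-flagged rows.
#' @param low_signal_quantile fraction of the typical signal below which a
#'   housekeeping gene is excluded (default 0.05).
#' @return tibble of class `hk_selection`: `feature_id`, `median_signal`,
#'   `threshold`, `retained`.
#' @export
select_housekeeping <- function(x, low_signal_quantile = 0.05) {
  hk <- x$feature_id[x$housekeeping]
  if (length(hk) < 2) abort("need >= 2 housekeeping-flagged features")
  m <- abundance_values(x)
  sample_medians <- apply(m, 2, stats::median, na.rm = TRUE)
  threshold <- low_signal_quantile * stats::median(sample_medians)
  med <- apply(m[hk, , drop = FALSE], 1, stats::median, na.rm = TRUE)
  retained <- med >= threshold
  if (!any(retained)) abort("all housekeeping genes fall below the low-signal threshold")
  n_drop <- sum(!retained)
  if (n_drop > 0) {
    inform(sprintf("excluding %d low-signal housekeeping gene(s): %s",
                   n_drop, paste(hk[!retained], collapse = ", ")))
  }
  structure(
    tibble(feature_id = hk, median_signal = unname(med),
           threshold = threshold, retained = retained),
    class = c("hk_selection", class(tibble()))
  )
}

#' Normalize a targeted panel by housekeeping geometric mean
#'
#' Within each sample, every abundance is divided by that sample's geometric
#' mean over the retained housekeeping genes; a single global scale factor —
#' the lowest multiple of `step` (default 100,000) leaving no log2 value
#' below 1 — then multiplies all values, and the result is log2-transformed.
#' By construction the per-sample log2 geometric mean of the retained
#' housekeeping genes equals `log2(factor)` exactly after normalization.
#'
#' @param x raw-scale [abundance_tbl()].
#' @param hk_ids retained housekeeping feature ids (defaults to
#'   [select_housekeeping()] on `x`).
#' @param step scale-factor step (default 1e5).
#' @return list with `matrix` (log2-scale [abundance_tbl()]) and
#'   `scale_factor` (tibble: `factor`, `step`, `min_log2_after`).
#' @export
normalize_housekeeping <- function(x, hk_ids = NULL, step = 1e5) {
  if (abundance_scale(x) != "raw") abort("expected a raw-scale matrix")
  if (is.null(hk_ids)) {
    sel <- select_housekeeping(x)
    hk_ids <- sel$feature_id[sel$retained]
  }
  m <- abundance_values(x)
  hk <- m[hk_ids, , drop = FALSE]
  bad <- which(colSums(is.na(hk) | hk <= 0) > 0)
  if (length(bad) > 0) {
    abort(sprintf("housekeeping value missing or <= 0 in sample '%s'",
                  colnames(m)[bad[1]]))
  }
  denom <- apply(hk, 2, geometric_mean)
  normed <- sweep(m, 2, denom, "/")
  min_val <- min(normed, na.rm = TRUE)
  # smallest k*step with log2(min_val * k*step) >= 1, i.e. k*step >= 2/min_val
  k <- max(1, ceiling(2 / min_val / step))
  factor <- k * step
  out <- log2(normed * factor)
  res <- tibble(factor = factor, step = step,
                min_log2_after = min(out, na.rm = TRUE))
  list(matrix = rebuild_abundance(out, x, scale = "log2"), scale_factor = res)
}

#' Pick the median sample by pairwise Pearson correlation
#'
#' Returns the sample maximizing the sum of Pearson correlations with all
#' other samples, each correlation computed on the log2 scale over features
#' present in both members of the pair. Ties break to the earlier sample in
#' column order.
#'
#' @param x an [abundance_tbl()] with >= 2 samples (log2-transformed
#'   internally when raw).
#' @return the chosen sample id (character scalar), with the per-sample
#'   correlation sums in attribute `cor_sums`.
#' @export
find_median_sample <- function(x) {
  m <- abundance_values(x)
  if (ncol(m) < 2) abort("need >= 2 samples")
  if (abundance_scale(x) == "raw") m <- log2(m)
  present <- !is.na(m)
  shared <- crossprod(present)
  diag(shared) <- 0
  isolated <- which(apply(shared, 1, max) < 3)
  if (length(isolated) > 0) {
    abort(sprintf("sample '%s' shares < 3 present features with every other sample",
                  colnames(m)[isolated[1]]))
  }
  cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  diag(cc) <- 0
  cc[is.na(cc)] <- 0  # pairs with < 2 shared features contribute nothing
  sums <- rowSums(cc)
  best <- which.max(sums)  # which.max takes the first maximum: earlier sample wins ties
  structure(colnames(m)[best], cor_sums = sums)
}

#' Rank-invariant (IRON-style) normalization of one sample against a reference
#'
#' Implements an intensity-dependent correction anchored on rank-stable
#' features. (1) Both vectors are ranked over shared present features;
#' iteratively, the `prune_fraction` of features with the largest absolute
#' rank difference is removed and the survivors re-ranked, for at most
#' `max_iter` passes or until the maximum rank difference stops shrinking —
#' the survivors are the rank-invariant set. (2) Over that set, the log2
#' offset (sample − reference) is fit as a sliding-window median (width
#' `window`) against mean log2 intensity, linearly interpolated between
#' anchors and held constant beyond the extreme anchors. (3) The interpolated
#' correction is subtracted from every feature of the sample.
#'
#' @param sample,reference numeric vectors of log2 intensities over the same
#'   features (named or positional); `NA` = missing.
#' @param max_iter maximum pruning passes (default 10).
#' @param prune_fraction fraction pruned per pass (default 0.05).
#' @param window sliding-median window, odd count (default 21).
#' @return list with `normalized` (corrected sample vector) and `curve`
#'   (tibble of class `iron_curve`: anchor `intensity`, `offset`; attributes
#'   `invariant_ids`, `reference_id`).
#' @export
iron_normalize <- function(sample, reference, max_iter = 10,
                           prune_fraction = 0.05, window = 21) {
  if (length(sample) != length(reference)) abort("vectors differ in length")
  shared <- which(!is.na(sample) & !is.na(reference))
  if (length(shared) < 20) abort("need >= 20 shared present features")
  idx <- shared
  prev_max <- Inf
  for (i in seq_len(max_iter)) {
    rd <- abs(rank(sample[idx]) - rank(reference[idx]))
    mx <- max(rd)
    if (mx == 0 || mx >= prev_max) break
    prev_max <- mx
    n_drop <- max(1L, floor(prune_fraction * length(idx)))
    if (length(idx) - n_drop < max(window, 10L)) break
    keep <- order(rd)[seq_len(length(idx) - n_drop)]
    idx <- sort(idx[keep])
  }
  invariant <- idx
  if (length(invariant) < window) {
    abort("rank-invariant set smaller than the window; use a smaller `window`")
  }
  intensity <- (sample[invariant] + reference[invariant]) / 2
  offset <- sample[invariant] - reference[invariant]
  o <- order(intensity)
  xs <- intensity[o]
  k <- min(window, length(xs) - (length(xs) + 1) %% 2)  # odd, <= n
  if (k %% 2 == 0) k <- k - 1
  ys <- stats::runmed(offset[o], k = k, endrule = "med")
  # evaluate each feature's correction at its mean intensity (the anchors'
  # coordinate); fall back to the sample value where the reference is missing
  xout <- ifelse(is.na(reference), sample, (sample + reference) / 2)
  correction <- stats::approx(xs, ys, xout = xout, rule = 2, ties = mean)$y
  normalized <- sample - correction
  curve <- structure(
    tibble(intensity = xs, offset = as.numeric(ys)),
    invariant_ids = if (!is.null(names(sample))) names(sample)[invariant] else invariant,
    class = c("iron_curve", class(tibble()))
  )
  list(normalized = normalized, curve = curve)
}

#' Normalize a proteomics matrix against its median sample
#'
#' Selects the reference with [find_median_sample()], log2-transforms the
#' matrix, and passes every other sample through [iron_normalize()] against
#' the reference. The reference column itself is only log2-transformed;
#' missing cells stay missing.
#'
#' @param x raw-scale [abundance_tbl()].
#' @inheritParams iron_normalize
#' @return list with `matrix` (log2-scale, normalized), `reference`
#'   (sample id) and `curves` (named list of per-sample `iron_curve`s).
#' @export
normalize_proteomics <- function(x, max_iter = 10, prune_fraction = 0.05,
                                 window = 21) {
  if (abundance_scale(x) != "raw") abort("expected a raw-scale matrix")
  ref <- find_median_sample(x)
  m <- log2(abundance_values(x))
  out <- m
  curves <- list()
  for (s in colnames(m)) {
    if (s == ref) next
    fit <- iron_normalize(m[, s], m[, ref], max_iter = max_iter,
                          prune_fraction = prune_fraction, window = window)
    out[, s] <- fit$normalized
    attr(fit$curve, "reference_id") <- ref
    curves[[s]] <- fit$curve
  }
  list(matrix = rebuild_abundance(out, x, scale = "log2"),
       reference = as.character(ref), curves = curves)
}
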