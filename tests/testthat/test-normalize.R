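test_that("geometric mean matches closed forms and rejects bad input", {
  expect_equal(geometric_mean(c(4, 1)), 2)
  expect_equal(geometric_mean(c(2, 4, 8)), 4)
  for (x in c(0.03, 1, 57.2)) expect_equal(geometric_mean(x), x)
  expect_error(geometric_mean(numeric()), "empty")
  expect_error(geometric_mean(c(1, 0)), "positive")
  expect_error(geometric_mean(c(1, -2)), "positive")
})

test_that("low-signal housekeeping genes are excluded, others retained", {
  g <- generate_mrna_panel(panel_spec(seed = 21))
  expect_message(sel <- select_housekeeping(g$matrix), "excluding 1")
  expect_equal(sum(sel$retained), 14)
  expect_equal(sel$feature_id[!sel$retained],
               g$truth$feature_id[g$truth$low_signal_hk])

  # all housekeeping genes with equal signal: none excluded
  flags <- data.frame(feature_id = sprintf("F%02d", 1:4),
                      housekeeping = c(TRUE, TRUE, FALSE, FALSE))
  x <- tiny_abund(rep(100, 12), 4, 3, flags = flags)
  expect_equal(sum(select_housekeeping(x)$retained), 2)
  # vacuous threshold keeps everything
  expect_true(all(select_housekeeping(g$matrix, 0)$retained))
})

test_that("scale factor is the lowest multiple of the step with min log2 >= 1", {
  mk <- function(min_val) {
    flags <- data.frame(feature_id = c("HK1", "HK2", "LOW"),
                        housekeeping = c(TRUE, TRUE, FALSE))
    tiny_abund(c(1, 1, min_val, 1, 1, min_val * 2), 3, 2, flags = flags,
               feature_ids = c("HK1", "HK2", "LOW"))
  }
  # boundary: 2e-5 * 1e5 = 2, log2 = 1 exactly, so 100,000 suffices
  r <- normalize_housekeeping(mk(2e-5), c("HK1", "HK2"))
  expect_equal(r$scale_factor$factor, 1e5)
  expect_equal(min(abundance_values(r$matrix)), 1)
  # 6.4e-6 needs >= 312,500; next multiple of 100,000 is 400,000
  r <- normalize_housekeeping(mk(6.4e-6), c("HK1", "HK2"))
  expect_equal(r$scale_factor$factor, 4e5)
})

test_that("scale-factor minimality holds on randomized panels", {
  for (seed in 1:8) {
    g <- generate_mrna_panel(panel_spec(n_features = 60, n_good = 4,
                                        n_poor = 4, n_housekeeping = 4,
                                        seed = seed))
    sel <- select_housekeeping(g$matrix)
    res <- normalize_housekeeping(g$matrix, sel$feature_id[sel$retained])
    fac <- res$scale_factor$factor
    out <- abundance_values(res$matrix)
    expect_gte(min(out), 1)
    expect_equal(fac %% 1e5, 0)
    if (fac > 1e5) {
      # one step lower must violate the rule
      expect_lt(min(out) - log2(fac) + log2(fac - 1e5), 1)
    }
    # algebraic identity: per-sample log2 geomean of retained housekeeping
    # genes equals log2(factor)
    hk <- out[sel$feature_id[sel$retained], ]
    expect_equal(unname(colMeans(hk)), rep(log2(fac), ncol(hk)),
                 tolerance = 1e-10)
  }
})

test_that("normalize_housekeeping names the offending sample on bad input", {
  flags <- data.frame(feature_id = c("HK1", "HK2"),
                      housekeeping = c(TRUE, TRUE))
  m <- matrix(c(1, NA, 1, 1), 2, 2,
              dimnames = list(c("HK1", "HK2"), c("SA", "SB")))
  x <- abundance_tbl(m, flags = flags, zero_as_missing = FALSE)
  expect_error(normalize_housekeeping(x, c("HK1", "HK2")), "sample 'SA'")
})

test_that("median sample maximizes the pairwise correlation sum", {
  # two identical samples and one anti-correlated: earlier of the pair wins
  base <- c(1, 2, 3, 4, 5)
  m <- cbind(S1 = base, S2 = base, S3 = rev(base))
  rownames(m) <- sprintf("F%d", 1:5)
  x <- abundance_tbl(m, scale = "log2")
  expect_equal(as.character(find_median_sample(x)), "S1")

  # all identical: first sample by the tie rule
  m2 <- cbind(A = base, B = base, C = base)
  rownames(m2) <- rownames(m)
  expect_equal(as.character(find_median_sample(abundance_tbl(m2, scale = "log2"))),
               "A")
})

test_that("median sample agrees with the brute-force correlation-sum oracle", {
  set.seed(31)
  m <- matrix(rnorm(200 * 6, 15, 2), 200, 6,
              dimnames = list(sprintf("F%03d", 1:200), sprintf("S%d", 1:6)))
  m[sample(length(m), 100)] <- NA
  x <- abundance_tbl(2^m, scale = "raw", zero_as_missing = FALSE)
  # oracle: direct O(n^2) loop over sample pairs
  sums <- numeric(6)
  for (i in 1:6) for (j in 1:6) {
    if (i == j) next
    ok <- !is.na(m[, i]) & !is.na(m[, j])
    sums[i] <- sums[i] + cor(m[ok, i], m[ok, j])
  }
  expect_equal(as.character(find_median_sample(x)),
               colnames(m)[which.max(sums)])

  # column-order invariance up to the tie rule
  perm <- c(4, 2, 6, 1, 3, 5)
  xp <- abundance_tbl(2^m[, perm], scale = "raw", zero_as_missing = FALSE)
  expect_equal(as.character(find_median_sample(xp)),
               as.character(find_median_sample(x)))
})

test_that("find_median_sample errors when a sample shares too few features", {
  m <- matrix(NA_real_, 5, 3,
              dimnames = list(sprintf("F%d", 1:5), c("A", "B", "C")))
  m[1:5, 1] <- 1:5; m[1:5, 2] <- 2:6; m[1:2, 3] <- 1:2
  x <- abundance_tbl(2^m, zero_as_missing = FALSE)
  expect_error(find_median_sample(x), "sample 'C' shares < 3")
})

test_that("IRON is the identity on self-normalization", {
  set.seed(1)
  ref <- sort(rnorm(300, 20, 3))
  names(ref) <- sprintf("F%03d", 1:300)
  fit <- iron_normalize(ref, ref)
  expect_equal(fit$normalized, ref)
  expect_true(all(abs(fit$curve$offset) < 1e-12))
})

test_that("IRON removes a constant log2 offset exactly", {
  set.seed(2)
  ref <- rnorm(500, 18, 2.5)
  names(ref) <- sprintf("F%03d", 1:500)
  sam <- ref + 1.7
  fit <- iron_normalize(sam, ref)
  inv <- attr(fit$curve, "invariant_ids")
  expect_lt(max(abs(fit$normalized[inv] - ref[inv])), 1e-6)
})

test_that("IRON removes a smooth intensity-dependent bias at interior features", {
  set.seed(3)
  ref <- sort(runif(1000, 12, 26))
  names(ref) <- sprintf("F%04d", seq_along(ref))
  bias <- function(x) 0.4 * sin((x - 12) / 14 * pi) + 0.02 * (x - 19)
  sam <- ref + bias(ref)
  fit <- iron_normalize(sam, ref)
  inv <- attr(fit$curve, "invariant_ids")
  interior <- inv[ref[inv] > quantile(ref, 0.05) & ref[inv] < quantile(ref, 0.95)]
  expect_lt(max(abs(fit$normalized[interior] - ref[interior])), 0.05)
})

test_that("IRON is idempotent to tolerance", {
  set.seed(4)
  ref <- rnorm(600, 20, 2)
  names(ref) <- sprintf("F%03d", seq_along(ref))
  sam <- ref + 1.2 + 0.3 * (ref - 20)^2 / 40
  once <- iron_normalize(sam, ref)
  twice <- iron_normalize(once$normalized, ref)
  expect_lt(max(abs(twice$curve$offset)), 1e-3)
})

test_that("IRON rejects undersized inputs with advice", {
  x <- rnorm(30); names(x) <- sprintf("F%d", 1:30)
  expect_error(iron_normalize(x[1:10], x[1:10]), ">= 20 shared")
  expect_error(iron_normalize(x, x + rnorm(30), window = 51), "smaller `window`")
})

test_that("proteomics normalization removes scale, keeps reference and missing", {
  set.seed(8)
  base <- 2^rnorm(400, 16, 2)
  m <- cbind(S1 = base, S2 = base * 3.5)  # proportional samples
  rownames(m) <- sprintf("F%03d", seq_len(nrow(m)))
  x <- abundance_tbl(m)
  res <- normalize_proteomics(x, window = 11)
  out <- abundance_values(res$matrix)
  expect_lt(abs(mean(out[, "S1"] - out[, "S2"])), 0.02)
  # reference column is log2 of the input, otherwise untouched
  expect_equal(out[, res$reference], log2(m[, res$reference]))

  g <- generate_proteomics(synthetic_spec(n_features = 300, seed = 10))
  r1 <- normalize_proteomics(g$matrix)
  r2 <- normalize_proteomics(g$matrix)
  expect_identical(abundance_values(r1$matrix), abundance_values(r2$matrix))
  # missing cells stay missing
  expect_identical(is.na(abundance_values(r1$matrix)),
                   is.na(abundance_values(g$matrix)))
})
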