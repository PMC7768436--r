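test_that("contaminant exclusion drops exactly the flagged rows", {
  flags <- data.frame(feature_id = sprintf("F%02d", 1:10),
                      bovine = rep(c(TRUE, FALSE), c(2, 8)),
                      reverse = c(rep(FALSE, 9), TRUE))
  x <- tiny_abund(rep(10, 20), 10, 2, flags = flags)
  suppressMessages(res <- exclude_contaminants(x))
  expect_equal(nrow(res$matrix), 7)
  expect_setequal(res$excluded$feature_id, c("F01", "F02", "F10"))

  clean <- tiny_abund(rep(10, 6), 3, 2)
  suppressMessages(res2 <- exclude_contaminants(clean))
  expect_equal(res2$matrix$feature_id, clean$feature_id)

  allbad <- tiny_abund(rep(10, 4), 2, 2,
                       flags = data.frame(feature_id = c("F01", "F02"),
                                          bovine = TRUE))
  expect_warning(suppressMessages(res3 <- exclude_contaminants(allbad)),
                 "all rows flagged")
  expect_equal(nrow(res3$matrix), 0)
})

test_that("Welch t matches hand computation and the t-CDF oracle", {
  r <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t_stat, 0)
  expect_equal(r$t_p, 1)

  # frozen from the Welch formulas plus numerical integration of the
  # t density: t = -1.0954451, df = 6, two-sided p = 0.3153336
  r <- welch_t(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(r$t_stat, -1.0954451, tolerance = 1e-7)
  expect_equal(r$t_df, 6)
  expect_equal(r$t_p, 0.3153336, tolerance = 1e-6)

  # antisymmetry
  s <- welch_t(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_equal(s$t_stat, -r$t_stat)
  expect_equal(s$t_p, r$t_p)

  # degenerate variances
  d <- welch_t(c(1, 1, 1), c(2, 2, 2))
  expect_equal(d$t_p, 0)
  expect_true(d$degenerate)
  expect_error(welch_t(1, c(1, 2)), ">= 2 values")
})

test_that("closed-form Hellinger equals the integration oracle", {
  expect_equal(hellinger_normal(0, 1, 0, 1), 0)
  expect_equal(hellinger_normal(0, 1, 1, 1), 0.34278725, tolerance = 1e-7)
  expect_equal(hellinger_normal(0, 1, 1, 1), hellinger_integral(0, 1, 1, 1),
               tolerance = 1e-7)
  # strictly increasing in |mu1 - mu2| at fixed sds
  h <- hellinger_normal(0, 1, seq(0, 5, by = 0.25), 1)
  expect_true(all(diff(h) > 0))
  # sd flooring keeps the result defined and bounded
  expect_true(hellinger_normal(0, 0, 1, 0) <= 1)

  set.seed(99)
  for (i in 1:50) {
    mu <- rnorm(2, 0, 3); s <- runif(2, 0.05, 3)
    expect_equal(hellinger_normal(mu[1], s[1], mu[2], s[2]),
                 hellinger_integral(mu[1], s[1], mu[2], s[2]),
                 tolerance = 1e-6)
  }
})

test_that("two-group table computes records, low-n handling and sorting", {
  set.seed(12)
  m <- matrix(rnorm(8 * 10, 15, 1), 8, 10,
              dimnames = list(sprintf("F%02d", 1:8), sprintf("S%02d", 1:10)))
  m[1, ] <- 15                      # identical in both groups
  m[2, ] <- m[2, ] + rep(c(0, 3), each = 5)   # strong effect
  m[3, 1:8] <- NA                   # low n in both groups
  design <- group_design(colnames(m), rep(c("poor", "good"), each = 5))
  norm <- abundance_tbl(m, scale = "log2", zero_as_missing = FALSE)
  tab <- two_group_table(norm, design)

  f1 <- tab[tab$feature_id == "F01", ]
  expect_equal(f1$log2_ratio, 0)
  expect_false(f1$passes)

  f2 <- tab[tab$feature_id == "F02", ]
  expect_true(f2$passes)
  expect_equal(f2$direction, "up_in_good")

  f3 <- tab[tab$feature_id == "F03", ]
  expect_false(f3$passes)
  expect_equal(f3$reason, "low_n")

  # sorted by |log2_ratio| descending
  expect_equal(order(-abs(tab$log2_ratio)), seq_len(nrow(tab)))
  # design referencing a missing sample errors
  bad <- group_design(c(colnames(m)[-1], "GHOST"),
                      rep(c("poor", "good"), each = 5))
  expect_error(two_group_table(norm, bad), "GHOST")
})

test_that("relabeling groups negates ratios and swaps direction lists", {
  g <- generate_proteomics(synthetic_spec(n_features = 300, seed = 6))
  suppressMessages(norm <- normalize_proteomics(g$matrix)$matrix)
  d1 <- g$design
  d2 <- group_design(d1$sample_id,
                     ifelse(d1$group == "good", "poor", "good"))
  t1 <- two_group_table(norm, d1)
  t2 <- two_group_table(norm, d2)
  t2m <- t2[match(t1$feature_id, t2$feature_id), ]
  expect_equal(t2m$log2_ratio, -t1$log2_ratio)
  expect_equal(t2m$t_p, t1$t_p)
  expect_equal(t2m$hellinger, t1$hellinger)
  s1 <- suppressMessages(split_directions(t1))
  s2 <- suppressMessages(split_directions(t2))
  expect_setequal(s1$up_in_good$feature_id, s2$up_in_poor$feature_id)
  expect_setequal(s1$up_in_poor$feature_id, s2$up_in_good$feature_id)
  expect_equal(nrow(s1$up_in_good) + nrow(s1$up_in_poor), sum(t1$passes))
})

test_that("null matrices pass the composite filter at most at alpha", {
  g <- generate_proteomics(synthetic_spec(n_features = 5000,
                                          frac_affected = 0, seed = 17))
  suppressMessages(norm <- normalize_proteomics(g$matrix)$matrix)
  tab <- two_group_table(norm, g$design)
  expect_lte(mean(tab$passes), 0.05)
})

test_that("planted effects are recovered with the right direction", {
  g <- generate_proteomics(synthetic_spec(n_features = 2000, seed = 23))
  suppressMessages(excl <- exclude_contaminants(g$matrix))
  suppressMessages(norm <- normalize_proteomics(excl$matrix)$matrix)
  tab <- two_group_table(norm, g$design)
  truth <- g$truth[match(tab$feature_id, g$truth$feature_id), ]
  aff <- truth$affected
  expect_gt(mean(tab$passes[aff]), 0.90)
  hit <- tab$passes & aff
  expect_gt(mean(tab$direction[hit] == truth$direction[hit]), 0.95)
})

test_that("Mann-Whitney matches enumeration and its two branches agree", {
  expect_equal(mann_whitney_exact(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(mann_whitney_exact(c(1, 2, 3), c(4, 5, 6)), 0.1)

  set.seed(41)
  for (i in 1:20) {
    a <- rnorm(4); b <- rnorm(5)
    expect_equal(mann_whitney_exact(a, b), mw_enum(a, b), tolerance = 1e-9)
  }
  # exact and approximate branches agree for moderate n
  set.seed(42)
  deltas <- replicate(30, {
    a <- rnorm(10); b <- rnorm(10, 0.5)
    exact <- mann_whitney_exact(a, b)
    approx <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    abs(exact - approx)
  })
  expect_lt(max(deltas), 0.01)
})
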