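test_that("midranks handle ties and always sum to n(n+1)/2", {
  expect_equal(rank_with_ties(c(10, 20, 30)), c(1, 2, 3))
  expect_equal(rank_with_ties(c(5, 5, 7)), c(1.5, 1.5, 3))
  expect_equal(rank_with_ties(c(3, 1, 4, 1, 5)), c(3, 1.5, 4, 1.5, 5))
  set.seed(1)
  for (i in 1:20) {
    v <- sample(1:5, 12, replace = TRUE)
    expect_equal(sum(rank_with_ties(v)), 12 * 13 / 2)
  }
  expect_error(rank_with_ties(c(1, NaN)), class = "eruptq_error_stats")
  expect_error(rank_with_ties(numeric(0)), class = "eruptq_error_stats")
})

test_that("spearman_rho matches the d^2 formula and handles edge cases", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, -(1:10)^3), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  set.seed(11)
  for (i in 1:30) {
    x <- sample(100, 15) # distinct -> no ties, d^2 formula exact
    y <- sample(100, 15)
    expect_equal(spearman_rho(x, y), spearman_d2(x, y), tolerance = 1e-12)
  }
  expect_warning(r <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
  expect_error(spearman_rho(1:2, 1:2), class = "eruptq_error_stats")
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  set.seed(12)
  for (i in 1:30) {
    x <- rnorm(20)
    y <- rnorm(20)
    r <- spearman_rho(x, y)
    expect_equal(spearman_rho(exp(x), y), r)
    expect_equal(spearman_rho(x, y^3 + 5 * y), r)
    expect_equal(spearman_rho(-1 / (x - min(x) + 1), y), r)
  }
})

test_that("Bonett-Wright interval is symmetric at zero and degenerate at one", {
  ci0 <- spearman_ci(0, 100)
  expect_equal(ci0$lcl, -ci0$ucl)
  ci1 <- spearman_ci(1, 50)
  expect_true(ci1$degenerate)
  expect_equal(c(ci1$lcl, ci1$ucl), c(1, 1))
  # closed form evaluated independently: z +/- 1.96 * sqrt((1+r^2/2)/(n-3))
  r <- 0.557; n <- 203
  se <- sqrt((1 + r^2 / 2) / (n - 3))
  lo <- tanh(atanh(r) - qnorm(0.975) * se)
  hi <- tanh(atanh(r) + qnorm(0.975) * se)
  ci <- spearman_ci(r, n)
  expect_equal(ci$lcl, lo)
  expect_equal(ci$ucl, hi)
  expect_true(ci$lcl < r && r < ci$ucl)
  expect_error(spearman_ci(0.5, 4), class = "eruptq_error_stats")
})

test_that("spearman_estimate bootstrap CI is deterministic and brackets rho", {
  set.seed(3)
  x <- rnorm(40)
  y <- x + rnorm(40)
  e1 <- spearman_estimate(x, y, ci_method = "bootstrap", n_boot = 400,
                          seed = 9)
  e2 <- spearman_estimate(x, y, ci_method = "bootstrap", n_boot = 400,
                          seed = 9)
  expect_identical(e1, e2)
  expect_true(e1$lcl <= e1$rho && e1$rho <= e1$ucl)
  expect_error(spearman_estimate(x, y, ci_method = "bootstrap"),
               class = "eruptq_error_stats")
})

test_that("alpha equals 1 for perfect within-unit agreement", {
  m <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, NA, 3, 4))
  expect_equal(as.numeric(krippendorff_alpha(m)), 1)
})

test_that("worked 4-unit interval example evaluates to 5/12", {
  m <- cbind(c(1, 2, 3, 1), c(1, 2, 3, 3))
  a <- krippendorff_alpha(m, "interval")
  expect_equal(as.numeric(a), 5 / 12, tolerance = 1e-12)
  expect_equal(as.numeric(a), brute_alpha(m), tolerance = 1e-12)
  expect_equal(attr(a, "n_pairable"), 8L)
})

test_that("alpha matches the enumeration oracle on random small matrices", {
  set.seed(21)
  tried <- 0
  while (tried < 60) {
    m <- random_ratings(sample(3:6, 1), sample(2:3, 1))
    kept <- m[rowSums(!is.na(m)) >= 2, , drop = FALSE]
    ok <- nrow(kept) >= 2 && length(unique(kept[!is.na(kept)])) >= 2
    if (!ok) next
    tried <- tried + 1
    expect_equal(as.numeric(krippendorff_alpha(m, "interval")),
                 brute_alpha(m, "interval"), tolerance = 1e-12)
  }
})

test_that("ratio-metric alpha matches the oracle and rejects c + k = 0", {
  set.seed(22)
  for (i in 1:20) {
    m <- random_ratings(5, 3, values = 1:4)
    if (sum(rowSums(!is.na(m)) >= 2) < 2) next
    expect_equal(as.numeric(krippendorff_alpha(m, "ratio")),
                 brute_alpha(m, "ratio"), tolerance = 1e-12)
  }
  expect_error(krippendorff_alpha(cbind(c(1, -1), c(-1, 2)), "ratio"),
               class = "eruptq_error_stats")
})

test_that("alpha metric invariances: affine for interval, scaling for ratio", {
  set.seed(23)
  m <- random_ratings(6, 3, values = 1:5)
  a_int <- as.numeric(krippendorff_alpha(m, "interval"))
  expect_equal(as.numeric(krippendorff_alpha(2.5 * m - 7, "interval")), a_int,
               tolerance = 1e-12)
  expect_equal(as.numeric(krippendorff_alpha(-3 * m, "interval")), a_int,
               tolerance = 1e-12)
  a_rat <- as.numeric(krippendorff_alpha(m, "ratio"))
  expect_equal(as.numeric(krippendorff_alpha(4 * m, "ratio")), a_rat,
               tolerance = 1e-12)
})

test_that("entirely-missing observer column does not change alpha", {
  m <- cbind(c(1, 2, 3, 1), c(1, 2, 3, 3))
  m3 <- cbind(m, c(NA, NA, NA, NA))
  expect_equal(as.numeric(krippendorff_alpha(m3)),
               as.numeric(krippendorff_alpha(m)))
})

test_that("units with fewer than two ratings are dropped and counted", {
  m <- rbind(c(1, 1), c(2, 2), c(3, NA), c(1, 3))
  a <- krippendorff_alpha(m)
  expect_equal(attr(a, "n_dropped"), 1L)
  expect_equal(attr(a, "n_units"), 3L)
  expect_equal(as.numeric(a), brute_alpha(m), tolerance = 1e-12)
})

test_that("degenerate pooled ratings yield a flagged NA alpha", {
  expect_warning(a <- krippendorff_alpha(cbind(c(1, 1), c(1, 1))),
                 "undefined")
  expect_true(is.na(a))
  expect_error(krippendorff_alpha(matrix(1:4, ncol = 1)),
               class = "eruptq_error_stats")
})

test_that("alpha is near zero for independently shuffled ratings", {
  set.seed(24)
  sims <- replicate(40, {
    v <- sample(0:3, 60, replace = TRUE)
    as.numeric(krippendorff_alpha(matrix(v, ncol = 2)))
  })
  expect_lt(abs(mean(sims)), 0.1)
})

test_that("alpha bootstrap CI: perfect agreement, determinism, bracketing", {
  perfect <- cbind(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  ci <- alpha_bootstrap_ci(perfect, n_boot = 100, seed = 5)
  expect_equal(c(ci$lcl, ci$ucl), c(1, 1))

  m <- cbind(c(1, 2, 3, 1), c(1, 2, 3, 3))
  ci1 <- alpha_bootstrap_ci(m, n_boot = 2000, seed = 77)
  ci2 <- alpha_bootstrap_ci(m, n_boot = 2000, seed = 77)
  expect_identical(ci1, ci2)
  expect_true(ci1$lcl <= 5 / 12 && 5 / 12 <= ci1$ucl)
  expect_error(alpha_bootstrap_ci(m, n_boot = 100),
               class = "eruptq_error_stats")
})

test_that("ratings matrices round-trip through wide CSV", {
  m <- cbind(r1 = c(1.25, NA, 3.5), r2 = c(1.25, 2, 3.25))
  rownames(m) <- c("u1", "u2", "u3")
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratings(m, path)
  m2 <- read_ratings(path)
  expect_equal(m2, m)
})
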