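test_that("design matrix has intercept, time and hinge columns", {
  X <- seg_design(c(1, 2, 3))
  expect_equal(unname(X), cbind(c(1, 1, 1), c(1, 2, 3)))

  X2 <- seg_design(c(1, 2, 3, 4), breakpoints = 2.5)
  expect_equal(unname(X2[, 3]), c(0, 0, 0.5, 1.5))

  # full rank whenever every segment contains samples
  t8 <- rep(1:8, each = 2)
  X3 <- seg_design(t8, breakpoints = c(2.5, 5.5))
  expect_equal(qr(X3)$rank, 4L)
})

test_that("design matrix rejects invalid breakpoints and times", {
  expect_error(seg_design(c(1, 2, 3), breakpoints = 3), "strictly inside")
  expect_error(seg_design(c(1, 2, 3), breakpoints = 0.5), "strictly inside")
  expect_error(seg_design(c(1, 2, 3, 4), breakpoints = c(3, 2)),
               "strictly increasing")
  expect_error(seg_design(c(3, 2, 1)), "sorted")
  expect_error(seg_design(c(2, 2, 2)), "distinct")
})

test_that("gaussian log-likelihood matches the closed form and the
           unsimplified Gaussian likelihood", {
  # rss = 10, n = 10 -> sigma^2 = 1 -> -(n/2) (log(2 pi) + 1)
  expect_equal(gaussian_loglik(10, 10), -5 * (log(2 * pi) + 1),
               tolerance = 1e-12)
  # independent evaluation of the unsimplified form
  full_loglik <- function(rss, n) {
    s2 <- rss / n
    -(n / 2) * log(2 * pi) - (n / 2) * log(s2) - rss / (2 * s2)
  }
  for (rss in c(0.3, 2, 57.1)) {
    for (n in c(5, 12, 40)) {
      expect_equal(gaussian_loglik(rss, n), full_loglik(rss, n),
                   tolerance = 1e-12)
    }
  }
  # monotone decreasing in rss; perfect fit is +Inf
  expect_gt(gaussian_loglik(5, 10), gaussian_loglik(10, 10))
  expect_identical(gaussian_loglik(0, 10), Inf)
})

test_that("k = 0 fit is ordinary least squares", {
  t <- as.numeric(1:10)
  m <- fit_segmented(2 + 3 * t, t, k = 0)
  expect_equal(m$intercept, 2, tolerance = 1e-9)
  expect_equal(m$slopes, 3, tolerance = 1e-9)
  expect_equal(m$rss, 0, tolerance = 1e-9)

  m2 <- fit_segmented(rep(5, 10), t, k = 0)
  expect_equal(m2$slopes, 0, tolerance = 1e-9)
  expect_equal(m2$intercept, 5, tolerance = 1e-9)
})

test_that("noiseless hinge is recovered exactly", {
  t <- as.numeric(1:20)
  y <- pmin(t, 10)  # slope 1 until t = 10, flat after
  m <- fit_segmented(y, t, k = 1)
  expect_true(m$converged)
  expect_equal(m$breakpoints, 10, tolerance = 1e-3 * 19)
  expect_equal(m$slopes, c(1, 0), tolerance = 1e-6)
  expect_equal(m$rss, 0, tolerance = 1e-8)
})

test_that("noiseless two-break profiles are recovered within tolerance", {
  t <- rep(1:20, each = 2)
  cases <- list(list(b = c(6, 14), s = c(1, -0.5, 2)),
                list(b = c(5.5, 12.5), s = c(-2, 0, 1.5)))
  for (cs in cases) {
    y <- oracle_piecewise_mean(t, cs$s, cs$b, intercept = 3)
    m <- fit_segmented(y, t, k = 2)
    expect_true(m$converged)
    expect_equal(m$breakpoints, cs$b, tolerance = 1e-3 * 19)
    expect_equal(m$slopes, cs$s, tolerance = 1e-4)
  }
})

test_that("fitted RSS never exceeds the midpoint-grid oracle", {
  set.seed(401)
  for (rep in 1:25) {
    n_t <- sample(8:14, 1)
    reps <- sample(1:2, 1)
    t <- rep(seq_len(n_t), each = reps)
    y <- rnorm(length(t))
    for (k in 1:2) {
      m <- fit_segmented(y, t, k, fit_control(seed = rep))
      o <- oracle_grid_fit(y, t, k)
      expect_true(m$converged)
      expect_lte(m$rss, o$rss * (1 + 1e-6))
    }
  }
})

test_that("best achievable RSS is non-increasing in k (grid oracle)", {
  set.seed(77)
  t <- rep(1:10, each = 2)
  for (rep in 1:10) {
    y <- rnorm(20, mean = 0.3 * t)
    r <- vapply(0:2, function(k) oracle_grid_fit(y, t, k)$rss, numeric(1))
    expect_true(all(diff(r) <= 1e-9))
  }
})

test_that("fits are continuous at breakpoints", {
  set.seed(5)
  t <- rep(1:12, each = 2)
  y <- oracle_piecewise_mean(t, c(2, -1), 6) + rnorm(24, 0, 0.3)
  m <- fit_segmented(y, t, k = 1)
  b <- m$breakpoints
  eps <- 1e-9
  expect_equal(predict(m, b - eps), predict(m, b + eps), tolerance = 1e-6)
})

test_that("prediction follows the piecewise-linear form", {
  t <- as.numeric(1:20)
  m <- fit_segmented(pmin(t, 10), t, k = 1)
  # flat beyond the breakpoint
  expect_equal(predict(m, 15), predict(m, m$breakpoints), tolerance = 1e-6)
  m0 <- fit_segmented(t, t, k = 0)
  expect_equal(unname(predict(m0, 7)), 7, tolerance = 1e-8)
  expect_error(predict_segmented(structure(list(converged = FALSE),
                                           class = "seg_model"), 1:3),
               "converge")
})

test_that("infeasible k and bad inputs error", {
  expect_error(fit_segmented(rnorm(3), c(1, 2, 3), k = 1), "infeasible")
  expect_error(fit_segmented(c(1, NA, 3), c(1, 2, 3), k = 0), "finite")
  expect_error(fit_segmented(rnorm(4), c(1, 2, 3), k = 0), "lengths differ")
})

test_that("replicated times enter as repeated rows, not averages", {
  t <- c(1, 1, 2, 2, 3, 3)
  y <- c(0, 2, 1, 3, 2, 4)  # mean line slope 1, intercept 0.?
  m <- fit_segmented(y, t, k = 0)
  ls <- stats::lm.fit(cbind(1, t), y)
  expect_equal(m$coef, unname(ls$coefficients), tolerance = 1e-10)
  expect_equal(m$rss, sum(ls$residuals^2), tolerance = 1e-10)
})
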