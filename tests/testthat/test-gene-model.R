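test_that("BIC reproduces the printed formula", {
  ll <- gaussian_loglik(10, 10)
  expect_equal(bic_score(ll, n = 10, k = 0), 3 * log(10) - 2 * ll,
               tolerance = 1e-12)
  # one extra breakpoint at equal likelihood costs 2 log(n)
  expect_equal(bic_score(-20, 25, 2) - bic_score(-20, 25, 1), 2 * log(25),
               tolerance = 1e-12)
})

test_that("model selection minimizes BIC with ties toward smaller k", {
  mk <- function(k, loglik, converged = TRUE) {
    structure(list(k = k, loglik = loglik, converged = converged),
              class = "seg_model")
  }
  n <- 20
  # only k = 0 converged
  expect_identical(select_model(list(mk(0, -5), mk(1, -1, FALSE)), n), 0L)
  # exact tie: equal BIC at k = 0 and k = 1
  ll1 <- -5 - log(n)  # BIC_1 = BIC_0
  expect_identical(select_model(list(mk(0, -5), mk(1, ll1)), n), 0L)
  # clearly better k = 1 wins
  expect_identical(select_model(list(mk(0, -50), mk(1, -5)), n), 1L)
  # nothing converged
  expect_identical(select_model(list(mk(0, -5, FALSE)), n), NA_integer_)
})

test_that("segment sample counts use half-open intervals, last closed", {
  expect_identical(segment_sample_counts(1:10, numeric(0)), 10L)
  expect_identical(segment_sample_counts(1:10, 6.5), c(6L, 4L))
  # a sample exactly at the breakpoint belongs to the right segment
  expect_identical(segment_sample_counts(1:10, 6), c(5L, 5L))
  t <- rep(1:4, each = 3)
  expect_identical(segment_sample_counts(t, c(1.5, 3.5)), c(3L, 6L, 3L))
})

test_that("minimum-segment guard demotes and cascades", {
  stub <- function(k, b, converged = TRUE) {
    structure(list(k = k, breakpoints = b, converged = converged),
              class = "seg_model")
  }
  times <- as.numeric(1:12)
  models <- list(stub(0, numeric(0)), stub(1, 9.5), stub(2, c(2.5, 9.5)))
  # k = 1 with 3 samples after the break -> reduced to 0
  expect_identical(enforce_min_segment(models, 1L, times, 5), 0L)
  # all segments >= mNS -> unchanged
  models_ok <- list(stub(0, numeric(0)), stub(1, 6.5))
  expect_identical(enforce_min_segment(models_ok, 1L, times, 5), 1L)
  # cascade: the k = 1 model also violates -> down to 0
  expect_identical(enforce_min_segment(models, 2L, times, 5), 0L)
  # a k = 2 model whose segments are all long is kept
  t20 <- as.numeric(1:20)
  models20 <- list(stub(0, numeric(0)), stub(1, 19.2),
                   stub(2, c(7.5, 13.5)))
  expect_identical(enforce_min_segment(models20, 2L, t20, 5), 2L)
  # non-converged intermediate candidates are skipped
  models_nc <- list(stub(0, numeric(0)), stub(1, 6.5, converged = FALSE),
                    stub(2, c(2.5, 9.5)))
  expect_identical(enforce_min_segment(models_nc, 2L, times, 5), 0L)
})

test_that("adjusted R-squared matches the printed formula", {
  expect_equal(adjusted_r_squared(0.9, 25, 2), 1 - 0.1 * 24 / 21,
               tolerance = 1e-12)
  expect_equal(adjusted_r_squared(1, 25, 2), 1)
  expect_equal(adjusted_r_squared(0, 10, 0), -0.125, tolerance = 1e-12)
  expect_error(adjusted_r_squared(0.5, 4, 2), "undefined")
})

test_that("slope p-values follow the heavy-tailed default reference", {
  # df = 1 is a Cauchy: p = 2 (0.5 - atan(|t|) / pi)
  expect_equal(segment_pvalue(2, 1), 2 * (0.5 - atan(2) / pi),
               tolerance = 1e-9)
  expect_equal(segment_pvalue(0, 1), 1)
  expect_equal(segment_pvalue(-2, 1), segment_pvalue(2, 1))
  # zero standard error
  expect_equal(segment_pvalue(1, 0), 0)
  expect_equal(segment_pvalue(0, 0), 1)
  # residual mode uses n - 2(k+1)
  expect_equal(segment_pvalue(2, 1, "residual", n = 20, k = 1),
               2 * stats::pt(-2, 16), tolerance = 1e-12)
  expect_error(segment_pvalue(2, 1, "residual", n = 4, k = 1), "df")
})

test_that("segment classification follows sign and p-value", {
  mk <- function(slopes, se) {
    structure(list(k = length(slopes) - 1L, slopes = slopes, slope_se = se,
                   n = 20, converged = TRUE), class = "seg_model")
  }
  # strong slopes are labeled by sign
  cls <- classify_segments(mk(c(100, -100), c(1, 1)), pval_cut = 0.1)
  expect_identical(cls$labels, c("up", "down"))
  expect_identical(cls$trend, "up-down")
  expect_identical(cls$table$code, c(1L, -1L))
  # weak slope -> no-change regardless of magnitude
  cls2 <- classify_segments(mk(3, 3), pval_cut = 0.1)
  expect_identical(cls2$labels, "same")
  # reducing pval_cut never converts "same" to "up"/"down"
  slopes <- seq(-5, 5, length.out = 11)
  se <- rep(1, 11)
  cuts <- c(0.3, 0.2, 0.1, 0.05, 0.01)
  prev_same <- rep(FALSE, 11)
  for (cut in cuts) {
    lab <- classify_segments(mk(slopes, se), pval_cut = cut)$labels
    now_same <- lab == "same"
    expect_true(all(now_same[prev_same]))
    prev_same <- now_same
  }
})

test_that("fit_gene composes the pipeline on canonical profiles", {
  ctl <- fit_control(seed = 11)
  t <- rep(1:10, each = 3)
  # noiseless increasing line -> k = 0, "up", perfect fit
  f <- fit_gene(2 * t + 1, t, ctl, "line")
  expect_identical(f$k_selected, 0L)
  expect_identical(f$trend_string, "up")
  expect_equal(f$adj_r2, 1, tolerance = 1e-9)
  # hinge up-then-flat with long segments -> k = 1, "up-same"
  y <- oracle_piecewise_mean(t, c(2, 0), 5.5)
  f2 <- fit_gene(y, t, ctl, "hinge")
  expect_identical(f2$k_selected, 1L)
  expect_identical(f2$trend_string, "up-same")
  expect_equal(f2$breakpoints, 5.5, tolerance = 1e-3 * 9)
  # pure noise -> poorly profiled
  set.seed(8)
  f3 <- fit_gene(rnorm(30), t, ctl, "noise")
  expect_lt(f3$adj_r2, 0.5)
})

test_that("selection recovers the true k on noiseless multi-segment data", {
  ctl <- fit_control(seed = 3)
  t <- rep(1:18, each = 2)
  cases <- list(list(s = 1.5, b = numeric(0)),
                list(s = c(2, -1), b = 9.5),
                list(s = c(1, -2, 0.5), b = c(6.5, 12.5)))
  for (cs in cases) {
    y <- oracle_piecewise_mean(t, cs$s, cs$b)
    f <- fit_gene(y, t, ctl)
    expect_identical(f$k_selected, length(cs$b))
  }
})

test_that("BIC trace reproduces the reported argmin under the tie rule", {
  set.seed(21)
  t <- rep(1:12, each = 2)
  for (i in 1:5) {
    y <- oracle_piecewise_mean(t, c(2, -1), 6.5) + rnorm(24, 0, 0.4)
    f <- fit_gene(y, t, fit_control(seed = i))
    bic <- f$bic_by_k
    # guard may have demoted below the argmin, never above
    argmin <- as.integer(names(bic)[which.min(bic)])
    expect_lte(f$k_selected, argmin)
    ms <- segment_sample_counts(t, f$breakpoints)
    expect_true(all(ms >= 5))
  }
})

test_that("fit_genes is deterministic and independent of gene order", {
  sim <- simulate_trends(n_genes = 6, n_times = 10, reps = 2, n_extra = 0,
                         noise = 0.3, seed = 14)
  f1 <- fit_genes(sim$matrix, sim$times, fit_control(seed = 9))
  f2 <- fit_genes(sim$matrix, sim$times, fit_control(seed = 9))
  expect_identical(results_table(f1), results_table(f2))
  # reversed gene order yields the same per-gene results
  f3 <- fit_genes(sim$matrix[rev(seq_len(6)), ], sim$times,
                  fit_control(seed = 9))
  expect_identical(results_table(f1),
                   results_table(f3)[order(match(results_table(f3)$gene_id,
                                                 results_table(f1)$gene_id)), ,
                                     drop = FALSE] |>
                     (\(d) { rownames(d) <- NULL; d })())
})
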