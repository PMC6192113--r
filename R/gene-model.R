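#' BIC of a segmented model
#'
#' Bayesian information criterion with the parameter count of a `k`-break
#' segmented model: `k` breakpoints, `k + 1` segment slopes, an intercept
#' and an error variance, i.e. `2k + 3` parameters:
#' `BIC = log(n) * (2k + 3) - 2 * loglik`. Lower is better.
#'
#' @param loglik Gaussian log-likelihood of the fit.
#' @param n Number of samples.
#' @param k Number of breakpoints.
#' @return The BIC value (`-Inf` for a perfect fit).
#' @examples
#' bic_score(gaussian_loglik(10, 10), n = 10, k = 0)
#' @export
bic_score <- function(loglik, n, k) {
  stopifnot(n >= 1, k >= 0)
  log(n) * (2 * k + 3) - 2 * loglik
}

#' Select the number of breakpoints by BIC
#'
#' Given the candidate models for `k = 0, 1, ..., K` (a list in increasing
#' `k` order), returns the `k` minimizing the BIC among converged models.
#' Ties are broken toward smaller `k`.
#'
#' @param models List of `"seg_model"` objects in increasing `k` order.
#' @param n Number of samples.
#' @return The selected integer `k`, or `NA` if no candidate converged.
#' @export
select_model <- function(models, n) {
  conv <- vapply(models, function(m) isTRUE(m$converged), logical(1))
  if (!any(conv)) return(NA_integer_)
  ks <- vapply(models, function(m) as.integer(m$k), integer(1))
  bic <- vapply(models, function(m) bic_score(m$loglik, n, m$k), numeric(1))
  bic[!conv] <- NA_real_
  ks[conv][which.min(bic[conv])]
}

#' Samples per segment
#'
#' Counts the samples falling in each segment induced by a set of
#' breakpoints. Segments are half-open `[lo, hi)` except the last, which is
#' closed at the final time, so every sample belongs to exactly one segment
#' and replicates count individually.
#'
#' @param times Numeric sample times (sorted).
#' @param breakpoints Numeric breakpoints (may be empty).
#' @return Integer vector of length `length(breakpoints) + 1`.
#' @examples
#' segment_sample_counts(1:10, breakpoints = 6.5)
#' @export
segment_sample_counts <- function(times, breakpoints) {
  k <- length(breakpoints)
  if (k == 0L) return(length(times))
  idx <- findInterval(times, breakpoints) + 1L
  tabulate(idx, nbins = k + 1L)
}

#' Enforce the minimum-samples-per-segment guard
#'
#' If any segment of the BIC-selected model contains fewer than `min_seg`
#' samples, the breakpoint count is decremented and the next-smaller
#' fitted model is checked in turn, down to `k = 0` if necessary. This is
#' the overfitting guard: a breakpoint supported by only a few trailing
#' samples is not retained.
#'
#' @param models List of `"seg_model"` objects in increasing `k` order
#'   (as fitted for one gene).
#' @param k_selected The BIC-selected breakpoint count.
#' @param times Numeric sample times.
#' @param min_seg Minimum samples per segment.
#' @return The (possibly reduced) breakpoint count.
#' @export
enforce_min_segment <- function(models, k_selected, times, min_seg) {
  k <- k_selected
  while (!is.na(k) && k > 0L) {
    m <- models[[k + 1L]]
    if (isTRUE(m$converged)) {
      cnt <- segment_sample_counts(times, m$breakpoints)
      if (all(cnt >= min_seg)) break
    }
    k <- k - 1L
  }
  k
}

#' Adjusted R-squared of the selected model
#'
#' `1 - (1 - R^2) * (n - 1) / (n - (k + 1) - 1)`, penalizing the fit
#' quality for the `k + 1` segment slopes. This is the quality gate used to
#' define top (dynamic) genes.
#'
#' @param r2 Ordinary R-squared of the selected model.
#' @param n Number of samples.
#' @param k_selected Selected breakpoint count.
#' @return Adjusted R-squared (can be negative).
#' @examples
#' adjusted_r_squared(0.9, n = 25, k_selected = 2)
#' @export
adjusted_r_squared <- function(r2, n, k_selected) {
  stopifnot(r2 <= 1 + 1e-12)
  den <- n - (k_selected + 1) - 1
  if (den <= 0) stop("adjusted R-squared undefined: n - k - 2 <= 0")
  1 - (1 - r2) * (n - 1) / den
}

#' Two-sided p-value of a segment slope
#'
#' Computes `t = slope / se` and its two-sided p-value. The default
#' reference distribution is the t-distribution with one degree of freedom
#' (a Cauchy), a deliberately heavy-tailed reference that only flags slopes
#' with large t-statistics as rising/falling; `df_mode = "residual"` uses
#' the conventional residual degrees of freedom `n - 2(k + 1)` instead.
#'
#' @param slope Slope estimate(s).
#' @param se Standard error(s), positive.
#' @param df_mode `"one"` or `"residual"`.
#' @param n,k Sample size and breakpoint count (needed for `"residual"`).
#' @return p-value(s) in `[0, 1]`.
#' @examples
#' segment_pvalue(2, 1)  # 2 * (0.5 - atan(2) / pi)
#' @export
segment_pvalue <- function(slope, se, df_mode = c("one", "residual"),
                           n = NULL, k = NULL) {
  df_mode <- match.arg(df_mode)
  df <- if (df_mode == "one") {
    1
  } else {
    if (is.null(n) || is.null(k)) stop("residual df needs `n` and `k`")
    dfr <- n - 2 * (k + 1)
    if (dfr < 1) stop("residual df < 1")
    dfr
  }
  p <- ifelse(se > 0,
              2 * stats::pt(-abs(slope / se), df),
              ifelse(slope == 0, 1, 0))
  p[is.na(slope) | is.na(se)] <- NA_real_
  p
}

.trend_code <- c(up = 1L, same = 0L, down = -1L)

#' Classify segment trends
#'
#' Labels each segment of a fitted model as `"up"`, `"down"` or `"same"`
#' (no-change): a segment whose slope p-value exceeds `pval_cut` is
#' `"same"`; otherwise the sign of the slope decides. Labels are also
#' encoded numerically as up = 1, down = -1, same = 0.
#'
#' @param model A converged `"seg_model"`.
#' @param pval_cut p-value cutoff.
#' @param df_mode Passed to [segment_pvalue()].
#' @param n Sample size (defaults to the model's).
#' @return A list with `labels` (character per segment), `trend` (the
#'   labels joined with `"-"`), and `table` (a data frame with slope, se,
#'   p-value, label and numeric code per segment).
#' @export
classify_segments <- function(model, pval_cut = 0.1,
                              df_mode = c("one", "residual"), n = model$n) {
  df_mode <- match.arg(df_mode)
  # a slope that is zero up to rounding error (relative to the other
  # slopes) is flat; without this, an interpolating fit (se = 0) would
  # label it by the sign of its ~1e-16 estimate
  slopes <- model$slopes
  slopes[abs(slopes) <= 1e-8 * max(abs(slopes), 1)] <- 0
  p <- segment_pvalue(slopes, model$slope_se, df_mode, n, model$k)
  lab <- ifelse(is.na(p) | p > pval_cut, "same",
                ifelse(slopes > 0, "up", "down"))
  list(labels = lab,
       trend = paste(lab, collapse = "-"),
       table = data.frame(segment = seq_along(lab),
                          slope = model$slopes,
                          slope_se = model$slope_se,
                          p_value = p,
                          trend = lab,
                          code = unname(.trend_code[lab]),
                          stringsAsFactors = FALSE))
}

#' Fit and summarize one gene
#'
#' The full per-gene pipeline: fit segmented models for
#' `k = 0 ... min(max_k, floor(N / min_seg) - 1)`, select `k` by BIC
#' (skipping non-converged candidates), apply the minimum-segment guard,
#' compute the adjusted R-squared of the retained model, and classify the
#' segment trends. Deterministic for a fixed `control$seed`.
#'
#' @param y Numeric expression values for one gene.
#' @param times Numeric sample times (sorted).
#' @param control A [fit_control()] object.
#' @param gene_id Label carried through to the result.
#' @return An object of class `"gene_fit"`: a list with `gene_id`,
#'   `k_selected`, `model`, `r2`, `adj_r2`, `bic_by_k`, `segments` (data
#'   frame), `segment_trends`, `trend_string`, `breakpoints`. If no
#'   candidate model converges, `k_selected` is `NA` and the gene is
#'   excluded downstream.
#' @examples
#' t <- rep(1:8, each = 3)
#' f <- fit_gene(0.5 * t + rnorm(24, 0, 0.01), t, gene_id = "demo")
#' f$trend_string
#' @export
fit_gene <- function(y, times, control = fit_control(), gene_id = "gene") {
  n <- length(y)
  kmax <- min(control$max_k,
              max(0L, as.integer(floor(n / control$min_seg)) - 1L),
              max(0L, as.integer(floor(n / 2)) - 1L))
  models <- lapply(0:kmax, function(k) fit_segmented(y, times, k, control))
  bic <- vapply(models, function(m) {
    if (isTRUE(m$converged)) bic_score(m$loglik, n, m$k) else NA_real_
  }, numeric(1))
  names(bic) <- as.character(0:kmax)
  k_sel <- select_model(models, n)
  if (is.na(k_sel)) {
    return(structure(list(gene_id = gene_id, k_selected = NA_integer_,
                          model = NULL, r2 = NA_real_, adj_r2 = NA_real_,
                          bic_by_k = bic, segments = NULL,
                          segment_trends = NULL, trend_string = NA_character_,
                          breakpoints = numeric(0)),
                     class = "gene_fit"))
  }
  k_sel <- enforce_min_segment(models, k_sel, times, control$min_seg)
  m <- models[[k_sel + 1L]]
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - m$rss / tss else 0
  adj <- if (n - k_sel - 2 > 0) adjusted_r_squared(r2, n, k_sel) else NA_real_
  cls <- classify_segments(m, control$pval_cut, control$df_mode, n)
  structure(list(gene_id = gene_id, k_selected = k_sel, model = m,
                 r2 = r2, adj_r2 = adj, bic_by_k = bic,
                 segments = cls$table, segment_trends = cls$labels,
                 trend_string = cls$trend,
                 breakpoints = m$breakpoints),
            class = "gene_fit")
}

#' @export
print.gene_fit <- function(x, ...) {
  cat("Gene", x$gene_id, "\n")
  if (is.na(x$k_selected)) {
    cat("  no converged model\n")
    return(invisible(x))
  }
  cat("  k =", x$k_selected, " adj R^2 =", signif(x$adj_r2, 4),
      " trend:", x$trend_string, "\n")
  if (x$k_selected > 0L) {
    cat("  breakpoints:", signif(x$breakpoints, 5), "\n")
  }
  invisible(x)
}

#' Fit every gene of an expression matrix
#'
#' Applies the mean-expression filter, then runs [fit_gene()] on every
#' remaining row. If `times` is unsorted, samples (matrix columns) are
#' reordered by time first, stably for ties. Each gene gets its own seed
#' derived from `control$seed` and the gene id, so results do not depend on
#' the order in which genes are processed.
#'
#' @param mat Numeric genes-by-samples matrix (rows named by gene).
#' @param times Numeric sample times, one per column.
#' @param control A [fit_control()] object.
#' @param filter Apply the mean-expression filter (`control$mean_cut`)
#'   before fitting? Default `TRUE`.
#' @return An object of class `"gene_fits"`: a named list of `"gene_fit"`
#'   objects with the (sorted) time vector attached as attribute `"times"`.
#' @examples
#' sim <- simulate_trends(n_genes = 3, seed = 4)
#' fits <- fit_genes(sim$matrix, sim$times)
#' vapply(fits, function(f) f$trend_string, "")
#' @export
fit_genes <- function(mat, times, control = fit_control(), filter = TRUE) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat)) stop("`mat` must be numeric")
  if (ncol(mat) != length(times)) {
    stop("`times` must have one value per matrix column")
  }
  if (is.unsorted(times)) {
    o <- order(times)
    times <- times[o]
    mat <- mat[, o, drop = FALSE]
  }
  if (is.null(rownames(mat))) {
    rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  }
  if (filter) {
    mat <- filter_low_expression(mat, control$mean_cut)$matrix
  }
  ids <- rownames(mat)
  fits <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    ctl <- control
    ctl$seed <- gene_seed(control$seed, ids[i])
    fits[[i]] <- fit_gene(mat[i, ], times, ctl, gene_id = ids[i])
  }
  names(fits) <- ids
  structure(fits, class = "gene_fits", times = times)
}

# Subset a gene_fits list while keeping class and attributes.
subset_fits <- function(fits, sel) {
  structure(unclass(fits)[sel], class = "gene_fits",
            times = attr(fits, "times"))
}

#' Per-gene results table
#'
#' One row per gene: selected breakpoint count, fit quality, trend string
#' and breakpoint locations (`";"`-joined).
#'
#' @param fits A `"gene_fits"` object.
#' @return A data frame.
#' @export
results_table <- function(fits) {
  data.frame(
    gene_id = vapply(fits, function(f) f$gene_id, character(1)),
    k = vapply(fits, function(f) as.integer(f$k_selected), integer(1)),
    adj_r2 = vapply(fits, function(f) as.numeric(f$adj_r2), numeric(1)),
    r2 = vapply(fits, function(f) as.numeric(f$r2), numeric(1)),
    trend = vapply(fits, function(f) as.character(f$trend_string),
                   character(1)),
    breakpoints = vapply(fits, function(f) {
      paste(signif(f$breakpoints, 8), collapse = ";")
    }, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Per-segment results table
#'
#' Long-format table with one row per fitted segment: slope, standard
#' error, p-value, trend label and numeric code.
#'
#' @param fits A `"gene_fits"` object.
#' @return A data frame.
#' @export
segments_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    if (is.null(f$segments)) return(NULL)
    cbind(gene_id = f$gene_id, f$segments, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), segment = integer(0),
                      slope = numeric(0), slope_se = numeric(0),
                      p_value = numeric(0), trend = character(0),
                      code = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
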