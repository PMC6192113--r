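#' Analysis parameters
#'
#' Collects every tunable parameter of the segmented-trend analysis in one
#' object, with the method's default values.
#'
#' @param max_k Maximum number of breakpoints considered per gene. Each gene
#'   is fitted with `k = 0, 1, ..., max_k` breakpoints (further capped by the
#'   feasibility rule `k <= floor(N / min_seg) - 1`) and the best `k` is
#'   chosen by BIC.
#' @param min_seg Minimum number of samples (replicates counted
#'   individually) required in every fitted segment ("mNS"). If the selected
#'   model leaves a shorter segment, the breakpoint count is decremented and
#'   the next-smaller model is used instead; this guards against overfitting.
#' @param pval_cut Two-sided p-value cutoff for classifying a segment slope
#'   as rising/falling rather than flat.
#' @param r2_cut Adjusted R-squared threshold above which a gene counts as a
#'   "top" (dynamic) gene.
#' @param mean_cut Mean-expression filter: genes whose row mean is not above
#'   this value are removed before fitting.
#' @param df_mode Degrees of freedom for the slope t-test. `"one"` (the
#'   default) compares the t-statistic to a t-distribution with a single
#'   degree of freedom (a Cauchy reference, deliberately heavy-tailed and
#'   conservative); `"residual"` uses the residual degrees of freedom
#'   `N - 2(k+1)`.
#' @param tol Convergence tolerance for the breakpoint iteration, relative
#'   to the observed time range.
#' @param max_iter Maximum breakpoint-update iterations per restart.
#' @param n_starts Number of restarts of the breakpoint iteration per gene
#'   and `k`; the first start is at evenly spaced quantiles of the time
#'   range, the rest are jittered.
#' @param seed Integer seed controlling the restart jitter (and, through
#'   [fit_genes()], the per-gene derived seeds).
#'
#' @return A list of class `"fit_control"`.
#' @examples
#' ctl <- fit_control(max_k = 2, pval_cut = 0.2)
#' ctl$max_k
#' @export
fit_control <- function(max_k = 3L, min_seg = 5L, pval_cut = 0.1,
                        r2_cut = 0.5, mean_cut = 5,
                        df_mode = c("one", "residual"),
                        tol = 1e-6, max_iter = 50L, n_starts = 5L,
                        seed = 71L) {
  df_mode <- match.arg(df_mode)
  max_k <- as.integer(max_k)
  min_seg <- as.integer(min_seg)
  stopifnot(max_k >= 0L, min_seg >= 2L,
            is.numeric(pval_cut), pval_cut > 0, pval_cut < 1,
            is.numeric(r2_cut), r2_cut >= 0, r2_cut <= 1,
            is.numeric(mean_cut), mean_cut >= 0,
            tol > 0, max_iter >= 1L, n_starts >= 1L)
  structure(list(max_k = max_k, min_seg = min_seg, pval_cut = pval_cut,
                 r2_cut = r2_cut, mean_cut = mean_cut, df_mode = df_mode,
                 tol = tol, max_iter = as.integer(max_iter),
                 n_starts = as.integer(n_starts),
                 seed = as.integer(seed)),
            class = "fit_control")
}
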