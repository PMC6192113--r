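#' Synthetic technical-replicate-like expression matrix
#'
#' Generates a trendless matrix emulating a set of technical replicates:
#' every sample is an independent draw around a gene-specific mean, with a
#' Poisson-like mean-variance relationship (`var = mu + phi * mu^2`) and
#' gene means spanning several orders of magnitude so that the
#' mean-expression filter removes a realistic fraction of genes. This is a
#' synthetic stand-in for a real technical-replicate RNA-seq dataset and
#' carries no trend by construction; it is the raw material for
#' [shuffle_null()].
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples (columns).
#' @param phi Overdispersion of the mean-variance relationship.
#' @param seed Integer seed.
#' @return A numeric genes-by-samples matrix (values clamped at 0).
#' @export
simulate_null_matrix <- function(n_genes = 2700, n_samples = 96,
                                 phi = 0.01, seed = 1) {
  with_seed(seed, {
    mu <- 2^runif(n_genes, 0, 9)
    sdv <- sqrt(mu + phi * mu^2)
    m <- matrix(rnorm(n_genes * n_samples, mean = rep(mu, n_samples),
                      sd = rep(sdv, n_samples)),
                nrow = n_genes, ncol = n_samples)
    m[m < 0] <- 0
    dimnames(m) <- list(sprintf("g%04d", seq_len(n_genes)),
                        sprintf("s%03d", seq_len(n_samples)))
    m
  })
}

# Time-assignment schemes for null simulations.
.null_times <- function(scheme, n_samples) {
  switch(scheme,
         even_short = as.numeric(seq_len(n_samples)),
         even_long = seq(1, by = 5, length.out = n_samples),
         random = sort(sample(5L * n_samples, n_samples)),
         stop("unknown scheme: ", scheme))
}

#' Null (trendless) dataset by sample shuffling
#'
#' Builds a no-true-trend dataset from a trendless source matrix (e.g.
#' technical replicates or [simulate_null_matrix()] output) by drawing
#' `n_samples` columns without replacement in permuted order and assigning
#' them time points. Any trend found in such data is a false positive.
#'
#' Time-assignment schemes: `"even_short"` (1, 2, ..., n), `"even_long"`
#' (1, 6, 11, ..., spacing 5), `"random"` (n values sampled without
#' replacement from 1..5n, sorted).
#'
#' @param mat Source genes-by-samples matrix with at least `n_samples`
#'   columns.
#' @param n_samples Number of columns to draw (default 25).
#' @param scheme Time-spacing scheme (see above).
#' @param seed Integer seed.
#' @return A `"sim_data"` list: `matrix`, `times`, `truth_k` (all zero),
#'   `truth_breaks` (empty), `truth_trends` (all `"same"`).
#' @export
shuffle_null <- function(mat, n_samples = 25,
                         scheme = c("even_short", "even_long", "random"),
                         seed = 1) {
  scheme <- match.arg(scheme)
  mat <- as.matrix(mat)
  if (n_samples > ncol(mat)) {
    stop("`n_samples` exceeds the number of available columns")
  }
  with_seed(seed, {
    idx <- sample(ncol(mat), n_samples)
    times <- .null_times(scheme, n_samples)
    g <- nrow(mat)
    structure(list(matrix = mat[, idx, drop = FALSE],
                   times = times,
                   truth_k = rep(0L, g),
                   truth_breaks = rep(list(numeric(0)), g),
                   truth_trends = rep(list("same"), g)),
              class = "sim_data")
  })
}

# Admissible sets of `k` true breakpoints on the grid of midpoints between
# consecutive distinct times: combinations whose induced segments all hold
# >= min_seg samples. Midpoints keep segment membership stable under small
# estimation error (a breakpoint placed exactly at an observed time would
# flip that time between segments on the sign of the error).
.break_grid <- function(times, k, min_seg) {
  ut <- unique(times)
  mids <- (ut[-1L] + ut[-length(ut)]) / 2
  if (k == 0L || length(mids) < k) return(list())
  combos <- utils::combn(mids, k, simplify = FALSE)
  Filter(function(b) all(segment_sample_counts(times, b) >= min_seg),
         combos)
}

# Draw segment slopes for given direction labels: 0 for "same", magnitude
# U(1, 3) otherwise, requiring adjacent slopes to differ by >= 1 so every
# true breakpoint is identifiable.
.draw_slopes <- function(dirs) {
  s <- numeric(length(dirs))
  for (i in seq_along(dirs)) {
    if (dirs[i] == "same") {
      s[i] <- 0
      next
    }
    sgn <- if (dirs[i] == "up") 1 else -1
    for (try in 1:25) {
      cand <- sgn * runif(1, 1, 3)
      if (i == 1L || abs(cand - s[i - 1L]) >= 1) break
    }
    if (i > 1L && abs(cand - s[i - 1L]) < 1) {
      cand <- if (abs(s[i - 1L]) <= 2) sgn * (abs(s[i - 1L]) + 1) else
        sgn * (abs(s[i - 1L]) - 1)
    }
    s[i] <- cand
  }
  s
}

#' Simulate genes with known piecewise-linear trends
#'
#' Generates an expression matrix whose genes follow continuous
#' piecewise-linear mean trajectories with a known number of breakpoints,
#' known breakpoint times and known segment directions, plus i.i.d.
#' Gaussian noise — the ground truth for validating breakpoint-count
#' selection, trend classification and breakpoint-time estimation.
#'
#' Per gene: the true breakpoint count is drawn uniformly from
#' `0..max_true_k`; breakpoints are drawn uniformly from the admissible
#' interior time grid (every induced segment keeps at least `min_seg`
#' samples); each segment direction is drawn from up/down/no-change
#' (adjacent no-change segments are excluded and adjacent slopes must
#' differ, so every true breakpoint is a real slope change); the
#' trajectory is vertically centered so all genes share the same mean
#' level. The default design is a 25-point time course (times `1..25`)
#' with 3 replicates per time point (N = 75 samples) and 50 genes.
#'
#' Noise presets: `"low"` (sd 0.15) and `"high"` (sd 1.0), expressed
#' relative to segment slopes of magnitude 1-3 per time unit; a numeric
#' `noise` is used as the sd directly.
#'
#' @param n_genes Number of genes.
#' @param n_times Number of distinct time points (values `1..n_times`).
#' @param reps Replicates per time point.
#' @param n_extra Extra replicates appended at the earliest time points.
#' @param max_true_k Maximum true breakpoint count (truth is uniform on
#'   `0..max_true_k`).
#' @param noise `"low"`, `"high"`, or a numeric Gaussian sd.
#' @param base_level Common mean expression level of every gene.
#' @param min_seg Minimum samples per true segment (should match the
#'   analysis `min_seg`).
#' @param seed Integer seed.
#' @return A `"sim_data"` list: `matrix` (genes x N), `times` (length N),
#'   `truth_k` (integer per gene), `truth_breaks` (list of numeric),
#'   `truth_trends` (list of character), `noise_sd`.
#' @examples
#' sim <- simulate_trends(n_genes = 2, noise = 0, seed = 3)
#' sim$truth_k
#' @export
simulate_trends <- function(n_genes = 50, n_times = 25, reps = 3,
                            n_extra = 0, max_true_k = 2, noise = "low",
                            base_level = 10, min_seg = 5, seed = 1) {
  sd_noise <- if (is.character(noise)) {
    switch(match.arg(noise, c("low", "high")), low = 0.15, high = 1.0)
  } else {
    stopifnot(is.numeric(noise), noise >= 0)
    noise
  }
  times <- rep(seq_len(n_times), each = reps)
  if (n_extra > 0) times <- sort(c(times, seq_len(n_extra)))
  times <- as.numeric(times)
  n <- length(times)
  grids <- lapply(seq_len(max_true_k), .break_grid,
                  times = times, min_seg = min_seg)
  feasible_k <- c(0L, which(vapply(grids, length, integer(1)) > 0L))
  if (max_true_k > 0L && length(feasible_k) < max_true_k + 1L) {
    stop("infeasible spacing: cannot place ", max_true_k,
         " breakpoints with min_seg = ", min_seg)
  }
  with_seed(seed, {
    truth_k <- sample(0:max_true_k, n_genes, replace = TRUE)
    truth_breaks <- vector("list", n_genes)
    truth_trends <- vector("list", n_genes)
    m <- matrix(NA_real_, n_genes, n)
    for (g in seq_len(n_genes)) {
      k <- truth_k[g]
      b <- if (k == 0L) numeric(0) else
        grids[[k]][[sample.int(length(grids[[k]]), 1L)]]
      repeat {
        dirs <- sample(c("up", "down", "same"), k + 1L, replace = TRUE)
        if (k == 0L || !any(dirs[-1L] == "same" & dirs[-(k + 1L)] == "same"))
          break
      }
      slopes <- .draw_slopes(dirs)
      mu <- slopes[1L] * times
      for (i in seq_len(k)) {
        mu <- mu + (slopes[i + 1L] - slopes[i]) * pmax(times - b[i], 0)
      }
      mu <- mu - mean(mu) + base_level
      m[g, ] <- mu + rnorm(n, 0, sd_noise)
      truth_breaks[[g]] <- as.numeric(b)
      truth_trends[[g]] <- dirs
    }
    dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                        sprintf("s%02d", seq_len(n)))
    structure(list(matrix = m, times = times, truth_k = as.integer(truth_k),
                   truth_breaks = truth_breaks, truth_trends = truth_trends,
                   noise_sd = sd_noise),
              class = "sim_data")
  })
}

# Align fits with simulation truth by gene id; errors on mismatch.
.truth_index <- function(fits, truth) {
  ids <- vapply(fits, function(f) f$gene_id, character(1))
  pos <- match(ids, rownames(truth$matrix))
  if (any(is.na(pos))) stop("gene ids in `fits` not found in `truth`")
  pos
}

#' Fraction of genes with correctly selected breakpoint count
#'
#' @param fits A `"gene_fits"` object fitted on a simulated dataset.
#' @param truth The `"sim_data"` object that generated the data.
#' @param by_k If `TRUE`, return the rate stratified by the true `k`.
#' @return A fraction in `[0, 1]` (or a named vector if `by_k`).
#' @export
correct_k_rate <- function(fits, truth, by_k = FALSE) {
  if (length(fits) == 0L) stop("no fits supplied")
  pos <- .truth_index(fits, truth)
  est <- vapply(fits, function(f) as.integer(f$k_selected), integer(1))
  tk <- truth$truth_k[pos]
  ok <- !is.na(est) & est == tk
  if (by_k) tapply(ok, tk, mean) else mean(ok)
}

#' Fraction of genes with fully correct trend
#'
#' A gene counts as correct only when its selected breakpoint count equals
#' the truth *and* every segment label (up/down/no-change) matches.
#'
#' @inheritParams correct_k_rate
#' @return A fraction in `[0, 1]` (or a named vector if `by_k`).
#' @export
trend_accuracy <- function(fits, truth, by_k = FALSE) {
  if (length(fits) == 0L) stop("no fits supplied")
  pos <- .truth_index(fits, truth)
  tk <- truth$truth_k[pos]
  ok <- vapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    !is.na(f$k_selected) && f$k_selected == tk[i] &&
      identical(as.character(f$segment_trends),
                as.character(truth$truth_trends[[pos[i]]]))
  }, logical(1))
  if (by_k) tapply(ok, tk, mean) else mean(ok)
}

#' Breakpoint-time estimation error
#'
#' Over the genes whose selected breakpoint count matches a true count of
#' at least one, pairs estimated and true breakpoints in sorted order and
#' returns the mean signed deviation (estimated minus true) and the mean
#' absolute deviation, in time units.
#'
#' @inheritParams correct_k_rate
#' @return A list with `mean_signed`, `mean_abs`, and `n` (number of
#'   breakpoint pairs). With no eligible genes, the means are `NA` and
#'   `n = 0`.
#' @export
breakpoint_deviation <- function(fits, truth) {
  pos <- .truth_index(fits, truth)
  devs <- numeric(0)
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    tk <- truth$truth_k[pos[i]]
    if (is.na(f$k_selected) || tk < 1L || f$k_selected != tk) next
    devs <- c(devs, sort(f$breakpoints) - sort(truth$truth_breaks[[pos[i]]]))
  }
  if (length(devs) == 0L) {
    return(list(mean_signed = NA_real_, mean_abs = NA_real_, n = 0L))
  }
  list(mean_signed = mean(devs), mean_abs = mean(abs(devs)),
       n = length(devs))
}
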