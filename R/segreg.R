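#' Validate an ordered time vector
#'
#' A time vector gives the ordered-condition value (hours, stages,
#' pseudotime, ...) of each sample. Replicated values are allowed; the
#' vector must be finite, sorted non-decreasing, and contain at least two
#' distinct values.
#'
#' @param times Numeric vector, one value per sample.
#' @return Invisibly, the sorted distinct time values.
#' @examples
#' check_times(c(1, 1, 2, 2, 3))
#' @export
check_times <- function(times) {
  if (!is.numeric(times) || length(times) < 2L) {
    stop("`times` must be a numeric vector with at least two samples")
  }
  if (any(!is.finite(times))) stop("`times` must be finite")
  if (is.unsorted(times)) {
    stop("`times` must be sorted non-decreasing; reorder the samples first")
  }
  ut <- unique(times)
  if (length(ut) < 2L) stop("`times` must contain at least two distinct values")
  invisible(ut)
}

#' Design matrix of the segmented linear model
#'
#' Builds the hinge-basis design for a piecewise-linear, continuous model:
#' an intercept column, the time itself, and one column
#' `max(t - b_i, 0)` per breakpoint `b_i`. The coefficient of each hinge
#' column is the *increment* in slope after its breakpoint, so the segment
#' slopes are the cumulative sums of the non-intercept coefficients and the
#' fitted curve is continuous at every breakpoint by construction.
#'
#' @param times Numeric sample times (sorted, replicates allowed).
#' @param breakpoints Numeric vector of breakpoints, strictly increasing and
#'   strictly inside the observed time range. May be empty.
#' @return An `N x (k + 2)` numeric matrix.
#' @examples
#' seg_design(c(1, 2, 3, 4), breakpoints = 2.5)
#' @export
seg_design <- function(times, breakpoints = numeric(0)) {
  ut <- check_times(times)
  k <- length(breakpoints)
  if (k > 0L) {
    if (any(!is.finite(breakpoints))) stop("breakpoints must be finite")
    if (k > 1L && any(diff(breakpoints) <= 0)) {
      stop("breakpoints must be strictly increasing")
    }
    if (breakpoints[1L] <= ut[1L] || breakpoints[k] >= ut[length(ut)]) {
      stop("breakpoints must lie strictly inside the observed time range")
    }
  }
  X <- cbind(1, times)
  if (k > 0L) X <- cbind(X, pmax(outer(times, breakpoints, "-"), 0))
  colnames(X) <- c("(Intercept)", "t",
                   if (k > 0L) paste0("hinge", seq_len(k)))
  X
}

#' Gaussian log-likelihood of a least-squares fit
#'
#' Maximized Gaussian log-likelihood given the residual sum of squares,
#' using the maximum-likelihood variance `sigma^2 = rss / n`:
#' `L = -(n/2) * (log(2 * pi * rss / n) + 1)`.
#'
#' A perfect fit (`rss = 0`) returns `Inf`; in BIC comparisons this is the
#' best possible value and ties are broken toward fewer breakpoints.
#'
#' @param rss Residual sum of squares (non-negative).
#' @param n Number of observations.
#' @return The log-likelihood (scalar; `Inf` when `rss = 0`).
#' @examples
#' gaussian_loglik(10, 10)  # -5 * (log(2*pi) + 1)
#' @export
gaussian_loglik <- function(rss, n) {
  stopifnot(is.numeric(rss), rss >= 0, n >= 1)
  if (rss == 0) return(Inf)
  -(n / 2) * (log(2 * pi * rss / n) + 1)
}

# Least-squares RSS of the pure hinge model at breakpoints `b`.
# Returns NULL when the design is rank deficient.
.hinge_rss <- function(y, times, b) {
  r <- cpp_hinge_rss(y, times, b)
  if (r < 0) NULL else r
}

# One restart of the iterative linearization for fixed k = length(b):
# alternate (i) least squares on the hinge design augmented with the gap
# covariates V_i = -1{t > b_i}, and (ii) the breakpoint update
# b_i <- b_i + gamma_i / delta_i (gap over hinge coefficient), with step
# halving whenever the proposed update would increase the hinge-model RSS,
# interval clamping, and a minimum inter-breakpoint gap. When even a
# vanishing step cannot improve the RSS the current point is accepted as
# converged.
#
# Identifiability guard: the gap covariate V_i is collinear with the other
# columns whenever fewer than two distinct times fall in (b_i, b_{i+1}]
# (the stretch where V_i is active but V_{i+1} is not), or, for the first
# breakpoint, when fewer than two distinct times lie at or below it. Such
# breakpoints are held fixed for the iteration (their V dropped); they
# become movable again once a neighbour moves away. Restarts whose designs
# lose rank anyway, or whose hinge coefficient vanishes, are reported as
# failed.
.seg_iterate <- function(y, times, ut, b, lo, hi, tol_abs, max_iter,
                         min_gap) {
  res <- cpp_seg_iterate(y, times, ut, b, lo, hi, tol_abs, max_iter,
                         min_gap)
  if (isTRUE(res$ok)) res$b <- drop(res$b)
  res
}

# Coarse global searches over inter-time midpoints, used to initialize one
# or two extra restarts (and as a floor on the returned RSS); they keep the
# local iteration out of poor basins.
#   - exhaustive: best hinge-RSS combination of midpoints, with the
#     candidate set thinned to at most `cap` combinations (k <= 2);
#   - greedy: extend the best (k-1)-point solution one breakpoint at a
#     time, scanning all midpoints at each step (k >= 2).
.grid_init <- function(y, times, ut, k, lo, hi, cap = 300L) {
  mids <- (ut[-1L] + ut[-length(ut)]) / 2
  mids <- mids[mids >= lo & mids <= hi]
  M <- length(mids)
  if (M < k) return(NULL)
  out <- list()
  if (k <= 2L) {
    cand <- mids
    if (choose(M, k) > cap) {
      m <- M
      while (m > k && choose(m - 1L, k) >= cap) m <- m - 1L
      cand <- mids[unique(round(seq(1L, M, length.out = m)))]
    }
    B <- utils::combn(cand, k)
    rs <- cpp_grid_rss(y, times, B)
    if (any(!is.na(rs))) {
      i <- which.min(rs)
      out[[length(out) + 1L]] <- list(b = B[, i], rss = rs[i])
    }
  }
  if (k >= 2L) {
    rs1 <- cpp_grid_rss(y, times, matrix(mids, nrow = 1L))
    if (any(!is.na(rs1))) {
      b <- mids[which.min(rs1)]
      ok <- TRUE
      for (j in seq_len(k - 1L)) {
        rest <- setdiff(mids, b)
        B <- vapply(rest, function(x) sort(c(b, x)),
                    numeric(length(b) + 1L))
        if (!is.matrix(B)) B <- matrix(B, nrow = length(b) + 1L)
        rs <- cpp_grid_rss(y, times, B)
        if (all(is.na(rs))) {
          ok <- FALSE
          break
        }
        b <- B[, which.min(rs)]
      }
      if (ok) {
        r <- cpp_hinge_rss(y, times, b)
        if (r >= 0) out[[length(out) + 1L]] <- list(b = b, rss = r)
      }
    }
  }
  if (length(out) == 0L) NULL else out
}

# Final least-squares fit at fixed breakpoints; computes coefficients,
# per-segment slopes with standard errors (breakpoints treated as fixed),
# RSS, Gaussian log-likelihood and fitted values.
.seg_finalize <- function(y, times, b, converged, n_iter) {
  n <- length(y)
  k <- length(b)
  X <- seg_design(times, b)
  p <- ncol(X)
  ft <- .lm.fit(X, y)
  if (ft$rank < p) converged <- FALSE
  cf <- ft$coefficients
  cf[!is.finite(cf)] <- 0
  fitted <- drop(X %*% cf)
  rss <- sum((y - fitted)^2)
  # an interpolating fit leaves only rounding error; snap it to zero so
  # BIC comparisons between perfect fits fall back to the smaller-k tie
  # rule instead of comparing rounding noise
  if (rss <= 1e-12 * max(sum(y^2), .Machine$double.eps)) rss <- 0
  slopes <- cumsum(cf[-1L])
  slope_se <- rep(NA_real_, k + 1L)
  if (ft$rank == p) {
    sigma2 <- rss / max(n - p, 1L)
    XtX <- crossprod(X)
    Vc <- tryCatch(sigma2 * solve(XtX), error = function(e) NULL)
    if (!is.null(Vc)) {
      L <- matrix(0, k + 1L, k + 1L)
      L[lower.tri(L, diag = TRUE)] <- 1
      Vs <- L %*% Vc[-1L, -1L, drop = FALSE] %*% t(L)
      slope_se <- sqrt(pmax(diag(Vs), 0))
    }
  }
  structure(list(
    k = k,
    intercept = unname(cf[1L]),
    coef = unname(cf),
    slopes = unname(slopes),
    slope_se = unname(slope_se),
    breakpoints = unname(b),
    rss = rss,
    loglik = gaussian_loglik(rss, n),
    fitted = fitted,
    converged = converged,
    n_iter = n_iter,
    n = n
  ), class = "seg_model")
}

# Non-converged placeholder used when every restart fails.
.seg_failed <- function(k, n) {
  structure(list(k = k, intercept = NA_real_, coef = rep(NA_real_, k + 2L),
                 slopes = rep(NA_real_, k + 1L),
                 slope_se = rep(NA_real_, k + 1L),
                 breakpoints = rep(NA_real_, k), rss = Inf, loglik = -Inf,
                 fitted = rep(NA_real_, n), converged = FALSE, n_iter = 0L,
                 n = n), class = "seg_model")
}

#' Fit a segmented regression with a fixed number of breakpoints
#'
#' Fits the continuous piecewise-linear model with `k` breakpoints to one
#' gene's expression values by iterative linearization: given current
#' breakpoints, the model is linearized with hinge terms `(t - b_i)_+` and
#' gap covariates `-1{t > b_i}`, fitted by least squares, and the
#' breakpoints updated by the ratio of the gap to the hinge coefficient
#' until the updates fall below `tol` (relative to the time range). Because
#' the iteration is local, it is restarted `n_starts` times from evenly
#' spaced and jittered initial breakpoints and the lowest-RSS converged
#' restart is kept. Breakpoints are continuous values, not snapped to
#' observed times.
#'
#' @param y Numeric expression values for one gene (finite, one per sample).
#' @param times Numeric sample times, sorted non-decreasing; replicated
#'   values enter as repeated design rows.
#' @param k Number of breakpoints (`>= 0`). `k = 0` is an ordinary
#'   least-squares line.
#' @param control A [fit_control()] object (uses `tol`, `max_iter`,
#'   `n_starts`, `seed`).
#' @return An object of class `"seg_model"`: a list with elements `k`,
#'   `intercept`, `coef` (intercept plus slope increments), `slopes`
#'   (the `k + 1` per-segment slopes), `slope_se`, `breakpoints`, `rss`,
#'   `loglik`, `fitted`, `converged`, `n_iter`, `n`. A model with
#'   `converged = FALSE` must be excluded from model selection.
#' @examples
#' t <- rep(1:10, each = 2)
#' y <- 2 + 3 * t
#' fit_segmented(y, t, k = 0)$slopes
#' @export
fit_segmented <- function(y, times, k, control = fit_control()) {
  if (!is.numeric(y) || any(!is.finite(y))) stop("`y` must be finite numeric")
  ut <- check_times(times)
  n <- length(y)
  if (length(times) != n) stop("`y` and `times` lengths differ")
  k <- as.integer(k)
  if (k < 0L) stop("`k` must be >= 0")
  if (n < 2L * (k + 1L)) {
    stop("infeasible k: need at least 2*(k+1) samples for k = ", k)
  }
  if (k == 0L) return(.seg_finalize(y, times, numeric(0), TRUE, 0L))

  T_ <- length(ut)
  rng <- ut[T_] - ut[1L]
  min_gap <- min(diff(ut))
  eps <- min_gap / 2
  lo <- ut[1L] + eps
  hi <- ut[T_] - eps
  if (!(lo < hi) || (k > 1L && (hi - lo) < (k - 1L) * min_gap)) {
    return(.seg_failed(k, n))
  }
  tol_abs <- control$tol * rng
  q <- ut[1L] + seq_len(k) / (k + 1) * rng
  half_gap <- rng / (k + 1) / 2
  ginit <- .grid_init(y, times, ut, k, lo, hi)
  best <- NULL
  with_seed(control$seed + 131L * k, {
    starts <- c(list(q),
                lapply(seq_len(control$n_starts - 1L), function(s) {
                  sort(q + runif(k, -half_gap, half_gap))
                }),
                lapply(ginit, `[[`, "b"))
    for (b0 in starts) {
      b0 <- pmin(pmax(b0, lo), hi)
      if (k > 1L && any(diff(b0) < min_gap * 0.999)) next
      res <- .seg_iterate(y, times, ut, b0, lo, hi, tol_abs,
                          control$max_iter, min_gap)
      if (res$ok && (is.null(best) || res$rss < best$rss)) best <- res
    }
  })
  # never return a worse fit than the plain least squares at the best
  # midpoint combination found by the coarse searches
  for (gi in ginit) {
    if (is.finite(gi$rss) && (is.null(best) || gi$rss < best$rss)) {
      best <- list(b = sort(gi$b), rss = gi$rss, n_iter = 0L)
    }
  }
  if (is.null(best)) return(.seg_failed(k, n))
  .seg_finalize(y, times, best$b, TRUE, best$n_iter)
}

#' @export
print.seg_model <- function(x, ...) {
  cat("Segmented model: k =", x$k,
      if (!x$converged) "(not converged)" else "", "\n")
  if (x$k > 0L) cat("  breakpoints:", signif(x$breakpoints, 5), "\n")
  cat("  slopes:     ", signif(x$slopes, 5), "\n")
  cat("  rss:", signif(x$rss, 6), " loglik:", signif(x$loglik, 6), "\n")
  invisible(x)
}

#' Predict from a segmented model
#'
#' Evaluates the continuous piecewise-linear fit at arbitrary times.
#'
#' @param object A `"seg_model"` from [fit_segmented()].
#' @param times Numeric times at which to evaluate (need not be the
#'   original sample times).
#' @param ... Ignored.
#' @return Numeric vector of fitted values.
#' @examples
#' t <- rep(1:10, each = 2)
#' m <- fit_segmented(2 + 3 * t, t, k = 0)
#' predict(m, c(1.5, 7))
#' @export
predict.seg_model <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$fitted)
  cf <- object$coef
  b <- object$breakpoints
  out <- cf[1L] + cf[2L] * times
  for (i in seq_along(b)) out <- out + cf[i + 2L] * pmax(times - b[i], 0)
  out
}

#' @rdname predict.seg_model
#' @param model A `"seg_model"` object.
#' @export
predict_segmented <- function(model, times) {
  if (!isTRUE(model$converged)) stop("model did not converge")
  predict(model, times)
}
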