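#' Top dynamic genes
#'
#' Keeps the genes whose selected model has adjusted R-squared above the
#' cutoff; these are the well-profiled, "dynamic" genes used for the global
#' summaries. Order is preserved. Genes without a converged model never
#' pass.
#'
#' @param fits A `"gene_fits"` object.
#' @param r2_cut Adjusted R-squared cutoff (default 0.5).
#' @return A `"gene_fits"` object with the passing subset.
#' @export
top_genes <- function(fits, r2_cut = 0.5) {
  sel <- vapply(fits, function(f) {
    !is.null(f$adj_r2) && !is.na(f$adj_r2) && f$adj_r2 > r2_cut
  }, logical(1))
  subset_fits(fits, sel)
}

# Nearest distinct observed time for each continuous breakpoint;
# equidistant ties go to the earlier time.
bin_breakpoints <- function(b, distinct_times) {
  vapply(b, function(x) {
    distinct_times[which.min(abs(distinct_times - x))]
  }, numeric(1))
}

#' Breakpoint distribution over time points
#'
#' Global summary of expression dynamics: each gene's (continuous)
#' breakpoints are assigned to the nearest distinct observed time
#' (equidistant ties to the earlier time) and counted per time point.
#' Time points with high counts mark transcriptome-wide transitions.
#' Typically computed on [top_genes()] output.
#'
#' @param fits A `"gene_fits"` object (usually the top genes).
#' @param times Sample times; defaults to the times attached to `fits`.
#' @return A data frame with columns `time` (the distinct times) and
#'   `count`.
#' @export
breakpoint_distribution <- function(fits, times = attr(fits, "times")) {
  ut <- check_times(times)
  counts <- integer(length(ut))
  for (f in fits) {
    b <- f$breakpoints
    if (length(b) == 0L) next
    bt <- bin_breakpoints(b, ut)
    counts <- counts + vapply(ut, function(t) sum(bt == t), integer(1))
  }
  data.frame(time = ut, count = counts)
}

#' Encoded trend matrix
#'
#' Encodes each gene's fitted trend over the distinct time points as
#' 1 (up), -1 (down), 0 (no-change): every time point receives the code of
#' the segment containing it, with breakpoints binned to the nearest
#' observed time (segments half-open on the left, i.e. a time equal to a
#' binned breakpoint starts the next segment). The matrix is suitable for
#' external clustering (e.g. `hclust`). Genes without a converged model
#' are dropped with a warning.
#'
#' @param fits A `"gene_fits"` object.
#' @param times Sample times; defaults to the times attached to `fits`.
#' @return An integer genes-by-T matrix with values in `{1, -1, 0}`,
#'   rows named by gene, columns by distinct time.
#' @export
trend_matrix <- function(fits, times = attr(fits, "times")) {
  ut <- check_times(times)
  ok <- vapply(fits, function(f) !is.na(f$k_selected), logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " gene(s) without a converged model dropped")
  }
  fits <- subset_fits(fits, ok)
  out <- matrix(0L, nrow = length(fits), ncol = length(ut),
                dimnames = list(vapply(fits, function(f) f$gene_id,
                                       character(1)),
                                as.character(ut)))
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    codes <- unname(.trend_code[f$segment_trends])
    if (length(f$breakpoints) == 0L) {
      out[i, ] <- codes[1L]
    } else {
      bt <- sort(bin_breakpoints(f$breakpoints, ut))
      seg <- findInterval(ut, bt) + 1L
      out[i, ] <- codes[seg]
    }
  }
  out
}

#' Extract genes matching an expression pattern
#'
#' Finds the genes whose fitted trend string matches a query pattern
#' exactly, e.g. `"up-down-up-down"` for cycling genes or
#' `"same-up-down"` for a delayed peak. Optionally requires the first
#' breakpoint to occur strictly after a given time (e.g. a delayed peak
#' whose rise starts after a developmental stage of interest).
#'
#' @param fits A `"gene_fits"` object.
#' @param pattern Query string: `"-"`-joined tokens from
#'   `up`, `down`, `same`. Matching is exact on the number of segments.
#' @param after_time Optional: keep only genes whose first breakpoint is
#'   strictly after this time.
#' @return Character vector of matching gene ids.
#' @export
match_pattern <- function(fits, pattern, after_time = NULL) {
  toks <- strsplit(pattern, "-", fixed = TRUE)[[1L]]
  if (length(toks) == 0L || !all(toks %in% c("up", "down", "same"))) {
    stop("invalid pattern: tokens must be 'up', 'down' or 'same', ",
         "joined with '-'")
  }
  pattern <- paste(toks, collapse = "-")
  sel <- vapply(fits, function(f) {
    if (is.na(f$k_selected) || !identical(f$trend_string, pattern)) {
      return(FALSE)
    }
    if (!is.null(after_time) && length(f$breakpoints) > 0L) {
      return(f$breakpoints[1L] > after_time)
    }
    TRUE
  }, logical(1))
  vapply(subset_fits(fits, sel), function(f) f$gene_id, character(1),
         USE.NAMES = FALSE)
}
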