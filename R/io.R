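#' Read an expression matrix
#'
#' Reads a genes-by-samples matrix from a delimited text file with a
#' header row of sample ids and gene ids in the first column (or as row
#' names). The separator is inferred from the extension (`.csv` -> comma,
#' otherwise tab) unless given explicitly. Columns are kept in file order;
#' the caller is expected to supply the matching time vector and, if
#' needed, let [fit_genes()] reorder by time.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` (default) infers from the extension.
#' @return A numeric matrix with gene ids as row names.
#' @export
read_expression <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"", fill = FALSE)
  if (ncol(df) >= 1L && (is.character(df[[1L]]) || is.factor(df[[1L]]))) {
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  } else {
    ids <- rownames(df)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad)) {
    stop("non-numeric expression values in column(s): ",
         paste(colnames(df)[bad], collapse = ", "))
  }
  m <- as.matrix(df)
  if (any(!is.finite(m))) {
    w <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop("missing/non-finite value at gene '", ids[w[1L]],
         "', sample '", colnames(m)[w[2L]], "'")
  }
  if (any(m < 0)) {
    warning("negative expression values present; input is expected to be ",
            "normalized, non-negative expression")
  }
  rownames(m) <- ids
  m
}

#' Write an expression matrix
#'
#' Companion writer to [read_expression()]: header row of sample ids,
#' gene ids in a leading `gene` column.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path (`.csv` writes comma-separated, otherwise tab).
#' @param sep Optional explicit separator.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(mat, path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a time vector
#'
#' Reads one numeric time value per sample from a whitespace/newline
#' separated text file, or validates an inline numeric vector. The values
#' need not be sorted here; [fit_genes()] sorts samples by time (stably
#' for ties) together with the matrix columns.
#'
#' @param x File path or numeric vector.
#' @param n_expected Optional expected length (number of samples).
#' @return A numeric vector.
#' @export
read_times <- function(x, n_expected = NULL) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("time file not found: ", x)
    v <- tryCatch(scan(x, what = numeric(), quiet = TRUE),
                  error = function(e) stop("non-numeric time value in ", x))
  } else if (is.numeric(x)) {
    v <- as.numeric(x)
  } else {
    stop("`x` must be a file path or a numeric vector")
  }
  if (any(!is.finite(v))) stop("time values must be finite")
  if (!is.null(n_expected) && length(v) != n_expected) {
    stop("expected ", n_expected, " time values, got ", length(v))
  }
  v
}

#' Mean-expression filter
#'
#' Removes genes whose mean expression is not above `mean_cut`; lowly
#' expressed genes carry little trend information and inflate the fitting
#' cost.
#'
#' @param mat Numeric genes-by-samples matrix.
#' @param mean_cut Threshold on the row mean (kept if strictly greater).
#' @return A list: `matrix` (kept rows), `removed` (ids), `n_removed`,
#'   `n_kept`.
#' @export
filter_low_expression <- function(mat, mean_cut = 5) {
  stopifnot(mean_cut >= 0)
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) {
    rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  }
  keep <- rowMeans(mat) > mean_cut
  list(matrix = mat[keep, , drop = FALSE],
       removed = rownames(mat)[!keep],
       n_removed = sum(!keep),
       n_kept = sum(keep))
}

#' Write analysis results
#'
#' Writes the standard output files of an analysis to a directory:
#' `genes.tsv` (one row per gene), `segments.tsv` (one row per segment),
#' `breakpoint_distribution.tsv` (time, count over the top genes),
#' `trend_matrix.tsv` (genes x distinct-times encoded 1/-1/0 matrix,
#' header = time values), `config.txt` (the parameters used, as
#' `key=value` lines) and `log.txt` (gene counts through the pipeline).
#' All files are deterministic for a fixed seed/config, so reruns are
#' byte-identical.
#'
#' @param fits A `"gene_fits"` object.
#' @param out_dir Output directory (created if needed).
#' @param control The [fit_control()] used (echoed to `config.txt` and
#'   used for the top-gene cutoff).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(fits, out_dir, control = fit_control()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  p1 <- tsv(results_table(fits), "genes.tsv")
  p2 <- tsv(segments_table(fits), "segments.tsv")
  tops <- top_genes(fits, control$r2_cut)
  p3 <- tsv(breakpoint_distribution(tops), "breakpoint_distribution.tsv")
  ok <- vapply(fits, function(f) !is.na(f$k_selected), logical(1))
  tm <- trend_matrix(subset_fits(fits, ok))
  p4 <- tsv(data.frame(gene_id = if (nrow(tm)) rownames(tm) else character(0),
                       tm, check.names = FALSE),
            "trend_matrix.tsv")
  cfg <- file.path(out_dir, "config.txt")
  writeLines(paste0(names(unclass(control)), "=",
                    vapply(unclass(control), format, character(1))), cfg)
  lg <- file.path(out_dir, "log.txt")
  writeLines(c(
    paste0("genes_fitted=", length(fits)),
    paste0("genes_converged=",
           sum(vapply(fits, function(f) !is.na(f$k_selected), logical(1)))),
    paste0("top_genes=", length(tops)),
    paste0("total_breakpoints=",
           sum(vapply(fits, function(f) length(f$breakpoints), integer(1)))),
    paste0("seed=", control$seed)
  ), lg)
  invisible(c(p1, p2, p3, p4, cfg, lg))
}

#' Plot a gene's data and segmented fit
#'
#' Scatter of the observed expression against time, the fitted
#' piecewise-linear curve, and dashed vertical markers at the estimated
#' breakpoints. Writes a PNG when `path` is given, otherwise draws on the
#' current device.
#'
#' @param fit A `"gene_fit"` with a converged model.
#' @param y Observed expression values.
#' @param times Sample times.
#' @param path Optional PNG output path.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `path` (or `NULL`).
#' @export
plot_gene <- function(fit, y, times, path = NULL, ...) {
  if (is.na(fit$k_selected)) stop("gene has no converged model")
  if (!is.null(path)) {
    grDevices::png(path, width = 700, height = 500)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(times, y, pch = 16, col = "grey30",
                 xlab = "time", ylab = "expression",
                 main = sprintf("%s  (k = %d, %s)", fit$gene_id,
                                fit$k_selected, fit$trend_string), ...)
  grid_t <- seq(min(times), max(times), length.out = 200)
  graphics::lines(grid_t, predict(fit$model, grid_t), col = "firebrick",
                  lwd = 2)
  if (length(fit$breakpoints)) {
    graphics::abline(v = fit$breakpoints, lty = 2, col = "steelblue")
  }
  invisible(path)
}
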