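#' Time-domain consistency metrics between two signals
#'
#' Pointwise error summaries between two equally sampled signals: mean
#' absolute error, root mean squared error and maximum absolute error.
#' For any pair, `0 <= MAE <= RMSE <= ME`.
#'
#' @param a,b [nmm_ts()] objects (or numeric vectors) of equal length; if
#'   both are `nmm_ts`, their sampling rates must agree.
#' @return An object of class `error_metrics`: a named list with `mae`,
#'   `rmse`, `me` (mV).
#' @examples
#' compare_signals(c(1, 2), c(0, 0))  # mae 1.5, rmse sqrt(2.5), me 2
#' @export
compare_signals <- function(a, b) {
  va <- if (inherits(a, "nmm_ts")) a$values else as.numeric(a)
  vb <- if (inherits(b, "nmm_ts")) b$values else as.numeric(b)
  if (inherits(a, "nmm_ts") && inherits(b, "nmm_ts") && a$fs != b$fs)
    stop("sampling rates differ (", a$fs, " vs ", b$fs, " Hz)")
  if (length(va) != length(vb))
    stop("signal lengths differ (", length(va), " vs ", length(vb), ")")
  d <- abs(va - vb)
  structure(list(mae = mean(d), rmse = sqrt(mean(d^2)), me = max(d)),
            class = "error_metrics")
}

#' @export
print.error_metrics <- function(x, ...) {
  cat(sprintf("<error_metrics> MAE=%.4f  RMSE=%.4f  ME=%.4f (mV)\n",
              x$mae, x$rmse, x$me))
  invisible(x)
}
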