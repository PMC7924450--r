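#' @export
print.ccc <- function(x, digits = 4, ...) {
  kind <- if (x$conditional) "Conditional compression-complexity causality"
          else "Compression-complexity causality"
  cat(kind, "(source -> target)\n")
  cat(sprintf("  windows: %d  (L=%d, w=%d, delta=%d, B=%d)\n",
              x$n_windows, x$params$L, x$params$w, x$params$delta,
              x$params$B))
  cat(sprintf("  mean CCC: %s", format(x$mean_ccc, digits = digits)))
  if (!is.na(x$p_value)) {
    cat(sprintf("   p-value: %s (%s)   sign: %s",
                format.pval(x$p_value, digits = digits), x$significance,
                x$sign_label))
  }
  cat("\n")
  invisible(x)
}

#' Summarize a CCC fit
#'
#' @param object a `"ccc"` object from [ccc()].
#' @param ... unused.
#' @return an object of class `"summary.ccc"` with the window table,
#'   per-window spread, and the significance verdict.
#' @export
summary.ccc <- function(object, ...) {
  pw <- object$per_window
  structure(list(
    fit = object,
    window_stats = c(mean = mean(pw$ccc), sd = stats::sd(pw$ccc),
                     min = min(pw$ccc), max = max(pw$ccc)),
    mean_cc_x = mean(pw$cc_x),
    mean_cc_xy = mean(pw$cc_xy)
  ), class = "summary.ccc")
}

#' @export
print.summary.ccc <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  mean CC(dx|x_past):        %s\n",
              format(x$mean_cc_x, digits = digits)))
  cat(sprintf("  mean CC(dx|x_past,y_past): %s\n",
              format(x$mean_cc_xy, digits = digits)))
  ws <- x$window_stats
  cat(sprintf("  window CCC: sd %s, range [%s, %s]\n",
              format(ws["sd"], digits = digits),
              format(ws["min"], digits = digits),
              format(ws["max"], digits = digits)))
  invisible(x)
}

#' @export
coef.ccc <- function(object, ...) {
  c(mean_ccc = object$mean_ccc)
}

#' @export
as.data.frame.ccc <- function(x, ...) {
  x$per_window
}

#' Plot per-window causality values
#'
#' Plots the per-window CCC values against the window start index, with the
#' window mean as a horizontal reference.
#'
#' @param x a `"ccc"` object.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.ccc <- function(x, ...) {
  pw <- x$per_window
  graphics::plot(pw$start_index, pw$ccc, type = "b", pch = 16,
                 xlab = "window start index", ylab = "window CCC", ...)
  graphics::abline(h = 0, lty = 3)
  graphics::abline(h = x$mean_ccc, col = 2, lty = 2)
}
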