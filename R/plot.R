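#' Scree and morphospace plots
#'
#' Base-graphics views of a fitted morphospace: a scree barplot of percent
#' variance and a PC1/PC2 scatter with reference samples distinguished.
#'
#' @param x a `morphospace_model`.
#' @param which `"scatter"`, `"scree"` or both.
#' @param ... passed to the underlying plot calls.
#' @export
plot.morphospace_model <- function(x, which = c("scatter", "scree"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  if (length(which) > 1L) {
    op <- graphics::par(mfrow = c(1, length(which)))
    on.exit(graphics::par(op))
  }
  if ("scatter" %in% which) {
    is_ref <- x$role == "reference"
    graphics::plot(x$scores[, 1L], x$scores[, 2L],
                   pch = ifelse(is_ref, 1L, 19L),
                   col = ifelse(is_ref, "grey40", "firebrick"),
                   xlab = sprintf("PC1 - %.1f%%", x$var_pct[1L]),
                   ylab = sprintf("PC2 - %.1f%%", x$var_pct[2L]), ...)
    graphics::legend("topright", legend = c("reference", "input"),
                     pch = c(1L, 19L), col = c("grey40", "firebrick"), bty = "n")
  }
  if ("scree" %in% which) {
    graphics::barplot(x$var_pct, names.arg = seq_along(x$var_pct),
                      main = "Scree plot", xlab = "Principal component",
                      ylab = "Percent variation")
  }
  invisible(x)
}

#' Morphospace plot of a QC report
#'
#' PC1/PC2 scatter colored by cluster; reference samples are open circles,
#' input samples filled, discarded inputs crossed.
#'
#' @param x a `qc_report` produced by [run_qc()] or [screen_cohort()].
#' @param ... passed to `plot`.
#' @export
plot.qc_report <- function(x, ...) {
  if (is.null(x$model)) ms_validation("report carries no morphospace model")
  sc <- x$model$scores
  s <- x$samples
  cols <- grDevices::hcl.colors(max(s$cluster), "Dark 3")
  pch <- ifelse(s$role == "reference", 1L, ifelse(s$decision == "retain", 19L, 4L))
  graphics::plot(sc[, 1L], sc[, 2L], col = cols[s$cluster], pch = pch, lwd = 2,
                 xlab = sprintf("PC1 - %.1f%%", x$model$var_pct[1L]),
                 ylab = sprintf("PC2 - %.1f%%", x$model$var_pct[2L]), ...)
  graphics::legend("topright",
                   legend = c("reference", "input retained", "input discarded"),
                   pch = c(1L, 19L, 4L), bty = "n")
  invisible(x)
}
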