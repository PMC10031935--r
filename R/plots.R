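#' Plot an importance ranking with the RFE cut-off
#'
#' Horizontal bar chart of median permutation importance for the top
#' proteins, with a line marking the RFE-selected set size (the number of
#' markers maximizing the median cross-validated concordance).
#'
#' @param importance data.frame with columns \code{protein} and
#'   \code{median_importance} (e.g. from \code{\link{rfScreen}}).
#' @param rfe optional \linkS4class{RFEResult}; draws the cut-off line.
#' @param top number of proteins shown.
#' @param main plot title.
#' @return invisibly, the plotted data.frame.
#' @export
plotImportance <- function(importance, rfe = NULL, top = 20L,
                           main = "Permutation importance") {
  df <- importance[order(-importance$median_importance), ]
  df <- df[seq_len(min(top, nrow(df))), ]
  df <- df[rev(seq_len(nrow(df))), ]
  graphics::par(mar = c(4, 6, 2, 1))
  graphics::barplot(df$median_importance, names.arg = df$protein,
                    horiz = TRUE, las = 1, col = "steelblue",
                    xlab = "median importance (drop in Harrell's C)",
                    main = main, cex.names = 0.7)
  if (!is.null(rfe)) {
    cut <- nrow(df) - rfe@selectedSize + 0.5
    graphics::abline(h = cut * 1.2, col = "red", lwd = 2)
  }
  invisible(df)
}

#' Plot the RFE concordance curve
#'
#' Median cross-validated test concordance against the number of retained
#' proteins, with the selected size marked.
#'
#' @param rfe an \linkS4class{RFEResult}.
#' @param main plot title.
#' @return invisibly, the curve data.frame.
#' @export
plotRFECurve <- function(rfe, main = "Recursive feature elimination") {
  cv <- rfe@curve
  graphics::plot(cv$n_features, cv$median_test_c, type = "b", pch = 19,
                 xlab = "number of proteins", ylab = "median test C",
                 main = main)
  graphics::abline(v = rfe@selectedSize, col = "red", lty = 2)
  invisible(cv)
}
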