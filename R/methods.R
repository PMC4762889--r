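#' @export
print.awenh_config <- function(x, ...) {
  cat(sprintf("Simulation %s: spatial = %s, temporal = %s\n",
              x$name, x$spatial, x$temporal))
  invisible(x)
}

#' @export
print.awenh_litter <- function(x, ...) {
  d <- dim(x$input)
  cat(sprintf(
    "Annual litter-input series: %d plots x %d years (%d-%d), size classes %s cm\n",
    d[1], d[2], min(x$years), max(x$years),
    paste(x$size_classes, collapse = "/")))
  cat(sprintf("  mean annual litter input %.3f kg C m-2 yr-1 (last year)\n",
              mean(apply(x$input[, d[2], , , drop = FALSE], 1, sum))))
  invisible(x)
}

#' @export
print.awenh_sim <- function(x, ...) {
  cat(sprintf("Soil carbon simulation %s (%s climate, %s means)\n",
              x$config$name, x$config$spatial, x$config$temporal))
  cat(sprintf("  %d plots, years %d-%d\n", nrow(x$stocks),
              min(x$years), max(x$years)))
  cat(sprintf("  mean stock %d-%d: %.3f kg C m-2\n",
              max(x$years) - 4L, max(x$years),
              stock_mean(x, (max(x$years) - 4L):max(x$years))))
  invisible(x)
}

#' Summarize a soil-carbon simulation
#'
#' @param object An `awenh_sim`.
#' @param stock_window,change_window Reporting windows.
#' @param ... Unused.
#' @return A list of class `summary.awenh_sim`: mean stock over the stock
#'   window (kg C m^-2), per-region mean stocks, cumulative national change
#'   over the change window (Gg C) and the annual national change series.
#' @export
summary.awenh_sim <- function(object, stock_window = 2008:2012,
                              change_window = 2000:2012, ...) {
  cols <- intersect(as.character(stock_window), colnames(object$stocks))
  pm <- rowMeans(object$stocks[, cols, drop = FALSE])
  out <- list(
    config = object$config,
    stock_window = range(stock_window),
    change_window = range(change_window),
    mean_stock = mean(pm),
    region_stock = tapply(pm, object$plots$region, mean),
    cumulative_change = cumulative_national_change(object, change_window),
    national_series = national_series(object)
  )
  class(out) <- "summary.awenh_sim"
  out
}

#' @export
print.summary.awenh_sim <- function(x, ...) {
  cat(sprintf("Simulation %s (%s x %s)\n", x$config$name, x$config$spatial,
              x$config$temporal))
  cat(sprintf("  mean soil C stock %d-%d: %.3f kg C m-2\n",
              x$stock_window[1], x$stock_window[2], x$mean_stock))
  for (r in names(x$region_stock))
    cat(sprintf("    %-10s %.3f kg C m-2\n", r, x$region_stock[[r]]))
  cat(sprintf("  cumulative national change %d-%d: %.1f Gg C\n",
              x$change_window[1], x$change_window[2], x$cumulative_change))
  cat(sprintf("  mean annual national change over that window: %.1f Gg C yr-1\n",
              x$cumulative_change / (x$change_window[2] - x$change_window[1] + 1)))
  invisible(x)
}

#' Plot a soil-carbon simulation
#'
#' Two base-graphics panels: the landscape-mean stock trajectory and the
#' annual national stock-change series.
#'
#' @param x An `awenh_sim`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.awenh_sim <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  yrs <- as.integer(colnames(x$stocks))
  graphics::plot(yrs, colMeans(x$stocks), type = "l",
                 xlab = "year", ylab = "mean soil C stock (kg C m-2)",
                 main = sprintf("Simulation %s", x$config$name), ...)
  ns <- national_series(x)
  graphics::plot(yrs, ns, type = "h", xlab = "year",
                 ylab = "national change (Gg C yr-1)")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
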