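# Plotting of metastatement results: scatter with least-squares trend
# line, 1D histogram, 2D histogram. Every plot object exposes its data
# (points, bin counts, fit parameters) so downstream checks never have to
# parse an image. Figures are drawn with base graphics; the output format
# follows the save filename extension (png default, 300 dpi).

numeric_singles <- function(ens, statement, ignore = c("H")) {
  res <- evaluate_statement(statement, ens, ignore = ignore)
  vapply(res, function(x) {
    if (is_absent(x) || !is_numeric_meta(x) || x$structure != "single") NA_real_
    else as.numeric(x$payload)
  }, numeric(1))
}

#' Scatter plot of two metastatements
#'
#' Evaluates both statements per record, drops records ABSENT on either
#' axis pairwise, and optionally fits an ordinary least-squares trend line
#' y = a x + b with its R squared (1 - SSres/SStot).
#'
#' @param ens an `sdf_ensemble`
#' @param x_stmt,y_stmt statement strings or parsed trees; must yield
#'   numeric singles
#' @param trend fit and draw the trend line
#' @param save optional filename; the figure is written there
#' @param draw draw on the active device (set `FALSE` for data-only use)
#' @param ignore element ignore list for atom-wise builtins
#' @return a `confmeta_plot` object with elements `x`, `y`, `n` and (with
#'   `trend`) `fit` = list(slope, intercept, r_squared)
#' @export
sdf_scatter <- function(ens, x_stmt, y_stmt, trend = FALSE, save = NULL,
                        draw = !is.null(save), ignore = c("H")) {
  xs <- numeric_singles(ens, x_stmt, ignore)
  ys <- numeric_singles(ens, y_stmt, ignore)
  ok <- !is.na(xs) & !is.na(ys)
  x <- xs[ok]; y <- ys[ok]
  if (length(x) == 0L) stop("scatter: no record yields values on both axes")
  if (trend && length(x) < 2L) stop("scatter: trend line needs at least 2 points")
  fit <- NULL
  if (trend) {
    m <- stats::lm(y ~ x)
    ss_res <- sum(stats::residuals(m)^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
    fit <- list(slope = unname(stats::coef(m)[2]),
                intercept = unname(stats::coef(m)[1]),
                r_squared = r2)
  }
  out <- structure(list(type = "scatter", x = x, y = y, n = length(x), fit = fit,
                        xlab = stmt_label(x_stmt), ylab = stmt_label(y_stmt)),
                   class = "confmeta_plot")
  if (draw) draw_plot(out, save)
  out
}

#' 1D histogram of a metastatement
#'
#' Equal-width bins span the value range; the right-most bin edge is
#' inclusive, so the maximum falls in the last bin and the counts always
#' sum to the number of contributing records.
#'
#' @inheritParams sdf_scatter
#' @param stmt statement string or parsed tree
#' @param bins number of bins (default 20)
#' @return a `confmeta_plot` with `counts`, `breaks`, `n`
#' @export
sdf_hist1d <- function(ens, stmt, bins = 20L, save = NULL,
                       draw = !is.null(save), ignore = c("H")) {
  v <- numeric_singles(ens, stmt, ignore)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("histogram: no record yields a numeric value")
  b <- bin_values(v, bins)
  out <- structure(list(type = "hist1d", counts = b$counts, breaks = b$breaks,
                        n = length(v), xlab = stmt_label(stmt)),
                   class = "confmeta_plot")
  if (draw) draw_plot(out, save)
  out
}

#' 2D histogram (heatmap) of two metastatements
#'
#' @inheritParams sdf_scatter
#' @param bins integer length 1 or 2: bins per axis (e.g. `c(15, 15)`)
#' @return a `confmeta_plot` with `counts` (x-bins by y-bins matrix),
#'   `xbreaks`, `ybreaks`, `n`
#' @export
sdf_hist2d <- function(ens, x_stmt, y_stmt, bins = c(15L, 15L), save = NULL,
                       draw = !is.null(save), ignore = c("H")) {
  if (length(bins) == 1L) bins <- rep(bins, 2L)
  xs <- numeric_singles(ens, x_stmt, ignore)
  ys <- numeric_singles(ens, y_stmt, ignore)
  ok <- !is.na(xs) & !is.na(ys)
  x <- xs[ok]; y <- ys[ok]
  if (length(x) == 0L) stop("histogram: no record yields values on both axes")
  bx <- bin_values(x, bins[1])
  by <- bin_values(y, bins[2])
  counts <- matrix(0L, nrow = bins[1], ncol = bins[2])
  for (i in seq_along(x))
    counts[bx$index[i], by$index[i]] <- counts[bx$index[i], by$index[i]] + 1L
  out <- structure(list(type = "hist2d", counts = counts,
                        xbreaks = bx$breaks, ybreaks = by$breaks, n = length(x),
                        xlab = stmt_label(x_stmt), ylab = stmt_label(y_stmt)),
                   class = "confmeta_plot")
  if (draw) draw_plot(out, save)
  out
}

# Equal-width binning over [min, max], right-most edge inclusive.
bin_values <- function(v, bins) {
  bins <- as.integer(bins)
  if (bins < 1L) stop("bins must be >= 1")
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    idx <- rep(1L, length(v))
    counts <- integer(bins); counts[1] <- length(v)
    return(list(counts = counts, breaks = seq(lo, lo + 1, length.out = bins + 1L),
                index = idx))
  }
  w <- (hi - lo) / bins
  idx <- pmin(floor((v - lo) / w) + 1L, bins)
  counts <- tabulate(idx, nbins = bins)
  list(counts = counts, breaks = seq(lo, hi, length.out = bins + 1L), index = as.integer(idx))
}

stmt_label <- function(stmt) {
  if (is.character(stmt)) stmt else unparse_statement(stmt)
}

#' @export
print.confmeta_plot <- function(x, ...) {
  switch(x$type,
    scatter = {
      cat(sprintf("scatter: %d points\n", x$n))
      if (!is.null(x$fit))
        cat(sprintf("  trend: y = %.6g x + %.6g, R^2 = %.6g\n",
                    x$fit$slope, x$fit$intercept, x$fit$r_squared))
    },
    hist1d = cat(sprintf("1D histogram: %d values in %d bins\n", x$n, length(x$counts))),
    hist2d = cat(sprintf("2D histogram: %d values in %d x %d bins\n",
                         x$n, nrow(x$counts), ncol(x$counts))))
  invisible(x)
}

#' Draw a plot object on a device or into a file
#'
#' @param p a `confmeta_plot`
#' @param save optional filename; format from the extension (`.png` or
#'   `.pdf`; anything else falls back to png at 300 dpi)
#' @return the plot object, invisibly
#' @export
draw_plot <- function(p, save = NULL) {
  if (!is.null(save)) {
    ext <- tolower(tools::file_ext(save))
    if (ext == "pdf") grDevices::pdf(save, width = 7, height = 5)
    else grDevices::png(save, width = 2100, height = 1500, res = 300)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  switch(p$type,
    scatter = {
      graphics::plot(p$x, p$y, pch = 19, col = "#00000080",
                     xlab = p$xlab, ylab = p$ylab)
      if (!is.null(p$fit)) {
        graphics::abline(p$fit$intercept, p$fit$slope, col = "red", lwd = 2)
        graphics::legend("topright", bty = "n",
                         legend = sprintf("R² = %.3f", p$fit$r_squared))
      }
    },
    hist1d = {
      mids <- (p$breaks[-1] + p$breaks[-length(p$breaks)]) / 2
      graphics::barplot(p$counts, names.arg = signif(mids, 3), space = 0,
                        xlab = p$xlab, ylab = "count")
    },
    hist2d = {
      graphics::image(x = p$xbreaks, y = p$ybreaks, z = p$counts,
                      col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                      xlab = p$xlab, ylab = p$ylab, useRaster = TRUE)
    })
  invisible(p)
}
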