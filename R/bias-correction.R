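#' Fit an empirical quantile-mapping bias correction
#'
#' For every cell and calendar month, pairs the empirical quantiles of the
#' simulated series with those of the observed series over their common
#' (calibration) period. Applying the resulting monotone map to the
#' simulated series aligns its distribution with the observations. The map
#' is fitted on the factual run and transferred unchanged to the paired
#' counterfactual run, so the scenarios' difference signal is preserved and
#' the counterfactual is never calibrated against observations directly.
#'
#' @param simulated a [temperature_grid()] (typically a factual member).
#' @param observed a [temperature_grid()] on the same cells.
#' @param n_quantiles number of interior quantile anchors (default 99, the
#'   percentiles 1..99).
#' @return an object of class `bias_correction_map`: arrays `src` and `tgt`
#'   of dim (cells, 12 months, anchors) plus the anchor `probs`.
#' @export
fit_bias_correction <- function(simulated, observed, n_quantiles = 99L) {
  stopifnot(inherits(simulated, "temperature_grid"),
            inherits(observed, "temperature_grid"))
  if (nrow(simulated$tmax) != nrow(observed$tmax))
    stop_input("simulated and observed grids have different cell counts")
  if (n_quantiles < 2L) stop_input("`n_quantiles` must be >= 2")
  common <- as.Date(intersect(simulated$dates, observed$dates),
                    origin = "1970-01-01")
  if (length(common) == 0L)
    stop_input("simulated and observed series share no calibration period")
  si <- simulated$dates %in% common
  oi <- observed$dates %in% common
  mon_s <- date_month(simulated$dates[si])
  mon_o <- date_month(observed$dates[oi])

  probs <- seq_len(n_quantiles) / (n_quantiles + 1)
  n_cells <- nrow(simulated$tmax)
  src <- array(NA_real_, c(n_cells, 12L, n_quantiles))
  tgt <- array(NA_real_, c(n_cells, 12L, n_quantiles))
  for (m in 1:12) {
    sm <- which(si)[mon_s == m]
    om <- which(oi)[mon_o == m]
    if (length(sm) == 0L || length(om) == 0L) next
    for (cell in seq_len(n_cells)) {
      src[cell, m, ] <- quantile7(simulated$tmax[cell, sm], probs)
      tgt[cell, m, ] <- quantile7(observed$tmax[cell, om], probs)
    }
  }
  structure(list(src = src, tgt = tgt, probs = probs,
                 method = "empirical quantile mapping per cell x month, linear interpolation, linear tail extrapolation",
                 calibration = range(common)),
            class = "bias_correction_map")
}

#' @export
print.bias_correction_map <- function(x, ...) {
  cat("<bias_correction_map> ", dim(x$src)[1], " cells x 12 months x ",
      length(x$probs), " anchors\n  ", x$method, "\n  calibration ",
      format(x$calibration[1]), " to ", format(x$calibration[2]), "\n",
      sep = "")
  invisible(x)
}

# Monotone piecewise-linear map through (src, tgt) anchors with linear
# extrapolation from the two outermost anchors; collapses tied source
# anchors (degenerate distributions) to a constant shift.
#' @noRd
qmap_interp <- function(src, tgt, x) {
  ok <- !duplicated(src)
  s <- src[ok]; g <- tgt[ok]
  if (length(s) == 1L) return(x + (g[1] - s[1]))
  y <- stats::approx(s, g, xout = x, rule = 1)$y
  lo <- x < s[1]
  hi <- x > s[length(s)]
  if (any(lo)) {
    slope <- (g[2] - g[1]) / (s[2] - s[1])
    y[lo] <- g[1] + slope * (x[lo] - s[1])
  }
  if (any(hi)) {
    k <- length(s)
    slope <- (g[k] - g[k - 1]) / (s[k] - s[k - 1])
    y[hi] <- g[k] + slope * (x[hi] - s[k])
  }
  y
}

#' Apply a fitted bias-correction map to a temperature series
#'
#' Each value is replaced by its quantile-mapped counterpart for its cell
#' and calendar month (linear interpolation between anchors, linear
#' extrapolation beyond the outermost anchors so the upper tail, where
#' heatwaves live, is not censored). The transform is monotone, so the
#' within-month rank order of days is preserved.
#'
#' @param series a [temperature_grid()] (factual or counterfactual).
#' @param map a `bias_correction_map` fitted on the same cells.
#' @return a corrected [temperature_grid()] with scenario suffix
#'   `"_bc"`.
#' @export
apply_bias_correction <- function(series, map) {
  stopifnot(inherits(series, "temperature_grid"),
            inherits(map, "bias_correction_map"))
  n_cells <- nrow(series$tmax)
  if (dim(map$src)[1] != n_cells)
    stop_input("map was fitted on a different number of cells")
  mon <- date_month(series$dates)
  out <- series$tmax
  for (m in sort(unique(mon))) {
    idx <- mon == m
    if (anyNA(map$src[1, m, ]))
      stop_input("map has no anchors for calendar month ", m)
    for (cell in seq_len(n_cells)) {
      out[cell, idx] <- qmap_interp(map$src[cell, m, ], map$tgt[cell, m, ],
                                    series$tmax[cell, idx])
    }
  }
  temperature_grid(out, series$dates,
                   scenario = paste0(series$scenario, "_bc"),
                   member = series$member)
}

#' Export a bias-correction map as a long-format data.frame
#'
#' @param map a `bias_correction_map`.
#' @return data.frame with columns `cell`, `month`, `prob`, `src`, `tgt`.
#' @export
bias_correction_table <- function(map) {
  stopifnot(inherits(map, "bias_correction_map"))
  d <- dim(map$src)
  grid <- expand.grid(cell = seq_len(d[1]), month = 1:12,
                      prob = map$probs)
  grid$src <- as.vector(map$src)
  grid$tgt <- as.vector(map$tgt)
  grid[!is.na(grid$src), , drop = FALSE]
}
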