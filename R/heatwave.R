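#' Per-cell heatwave temperature thresholds
#'
#' The threshold for a cell is a percentile (default the 90th) of that
#' cell's warm-season (default May-October) daily tmax pooled over all
#' years of the series. Sample quantiles use linear interpolation between
#' order statistics (type 7); the convention is recorded in the result.
#'
#' @param grid a [temperature_grid()].
#' @param warm_months integer months defining the warm season (default
#'   `5:10`, May-October).
#' @param percentile quantile level in `(0, 1)` (default 0.9).
#' @return numeric vector of thresholds (degC), one per cell, with
#'   attributes `percentile`, `warm_months` and `quantile_type`.
#' @export
compute_threshold <- function(grid, warm_months = 5:10, percentile = 0.9) {
  stopifnot(inherits(grid, "temperature_grid"))
  if (length(warm_months) == 0L || !all(warm_months %in% 1:12))
    stop_input("`warm_months` must be a non-empty subset of 1:12")
  if (percentile <= 0 || percentile >= 1)
    stop_input("`percentile` must be in (0, 1)")
  warm <- date_month(grid$dates) %in% warm_months
  if (!any(warm)) stop_input("no warm-season days in the series")
  thr <- apply(grid$tmax[, warm, drop = FALSE], 1, quantile7,
               probs = percentile)
  structure(thr, percentile = percentile, warm_months = warm_months,
            quantile_type = 7L)
}

#' Detect heatwave days and events
#'
#' A heatwave is a run of at least `min_duration` (default 2) consecutive
#' days with tmax strictly above the cell's threshold. Runs are evaluated
#' on the full daily series, so events may cross month and year boundaries;
#' isolated exceedance days shorter than `min_duration` are not heatwave
#' days. Ties at the threshold are non-events (strict exceedance).
#'
#' @param grid a [temperature_grid()].
#' @param thresholds numeric vector of per-cell thresholds (degC), as from
#'   [compute_threshold()].
#' @param min_duration minimum run length in days (default 2).
#' @return an object of class `heatwave_mask`: list with `heatwave_day`
#'   (logical cells x days matrix), `events` (data.frame `cell`, `start`,
#'   `end`, `duration`), `dates`, `thresholds`.
#' @export
detect_heatwaves <- function(grid, thresholds, min_duration = 2L) {
  stopifnot(inherits(grid, "temperature_grid"))
  if (length(thresholds) != nrow(grid$tmax) || anyNA(thresholds))
    stop_input("need one finite threshold per cell")
  if (min_duration < 1L) stop_input("`min_duration` must be >= 1")

  n_cells <- nrow(grid$tmax)
  hw <- matrix(FALSE, n_cells, length(grid$dates))
  ev <- vector("list", n_cells)
  for (cell in seq_len(n_cells)) {
    exc <- grid$tmax[cell, ] > thresholds[cell]
    r <- rle(exc)
    keep <- r$values & r$lengths >= min_duration
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(keep)) hw[cell, starts[i]:ends[i]] <- TRUE
    if (any(keep))
      ev[[cell]] <- data.frame(cell = cell,
                               start = grid$dates[starts[keep]],
                               end = grid$dates[ends[keep]],
                               duration = r$lengths[keep])
  }
  events <- if (any(!vapply(ev, is.null, logical(1)))) {
    do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
  } else {
    data.frame(cell = integer(), start = as.Date(character()),
               end = as.Date(character()), duration = integer())
  }
  rownames(events) <- NULL
  structure(list(heatwave_day = hw, events = events, dates = grid$dates,
                 thresholds = thresholds),
            class = "heatwave_mask")
}

#' @export
print.heatwave_mask <- function(x, ...) {
  cat("<heatwave_mask> ", nrow(x$heatwave_day), " cells x ",
      length(x$dates), " days; ", nrow(x$events), " events, ",
      sum(x$heatwave_day), " heatwave days\n", sep = "")
  invisible(x)
}

#' Last-gestational-week heatwave exposure indicator
#'
#' A delivery day `d` is exposed when at least one heatwave day falls in
#' the trailing window `[d - window_days + 1, d]` (default 7 days, i.e.
#' the final gestational week, days d-6..d). At the start of the series
#' the window is truncated to the available days.
#'
#' @param mask a `heatwave_mask` from [detect_heatwaves()].
#' @param window_days trailing window length in days (default 7).
#' @return an object of class `exposure_field`: list with `exposed`
#'   (logical cells x days matrix), `dates`, `window_days`.
#' @export
exposure_window <- function(mask, window_days = 7L) {
  stopifnot(inherits(mask, "heatwave_mask"))
  window_days <- as.integer(window_days)
  if (window_days < 1L) stop_input("`window_days` must be >= 1")
  hw <- mask$heatwave_day
  n <- ncol(hw)
  cs <- t(apply(hw, 1, function(x) cumsum(as.integer(x))))
  if (n == 1L) cs <- matrix(cs, nrow = nrow(hw))
  lagged <- cbind(matrix(0L, nrow(hw), min(window_days, n)),
                  cs[, seq_len(max(0L, n - window_days)), drop = FALSE])
  structure(list(exposed = (cs - lagged) > 0, dates = mask$dates,
                 window_days = window_days),
            class = "exposure_field")
}

#' Heatwave-day counts per cell-year and national mean
#'
#' @param mask a `heatwave_mask`.
#' @param weights optional per-cell weights (e.g. population) for the
#'   national summary; the default is the unweighted mean over cells.
#' @return list with `by_cell_year` (integer cells x years matrix) and
#'   `national` (named numeric vector, mean heatwave days per cell-year).
#' @export
heatwave_days_by_year <- function(mask, weights = NULL) {
  stopifnot(inherits(mask, "heatwave_mask"))
  yr <- date_year(mask$dates)
  years <- sort(unique(yr))
  by_cell_year <- vapply(years, function(y)
    rowSums(mask$heatwave_day[, yr == y, drop = FALSE]),
    numeric(nrow(mask$heatwave_day)))
  by_cell_year <- matrix(as.integer(by_cell_year),
                         nrow = nrow(mask$heatwave_day),
                         dimnames = list(NULL, years))
  w <- weights %||% rep(1, nrow(by_cell_year))
  if (length(w) != nrow(by_cell_year))
    stop_input("`weights` must have one value per cell")
  national <- colSums(by_cell_year * w) / sum(w)
  list(by_cell_year = by_cell_year, national = national)
}
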