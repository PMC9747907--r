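# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Month number (1-12) for a Date vector.
#' @noRd
date_month <- function(dates) as.integer(format(dates, "%m"))

#' @noRd
date_year <- function(dates) as.integer(format(dates, "%Y"))

# Number of calendar days in the month containing each date (leap-aware).
#' @noRd
days_in_month <- function(year, month) {
  stopifnot(all(month %in% 1:12))
  first <- as.Date(sprintf("%04d-%02d-01", year, month))
  nxt_y <- ifelse(month == 12L, year + 1L, year)
  nxt_m <- ifelse(month == 12L, 1L, month + 1L)
  as.integer(as.Date(sprintf("%04d-%02d-01", nxt_y, nxt_m)) - first)
}

# Linear-interpolation sample quantile (type 7), the convention used for
# heatwave thresholds and empirical confidence intervals alike.
#' @noRd
quantile7 <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}

# Deterministic per-(stream, cell) substream seed below 2^31.
#' @noRd
substream_seed <- function(master, stream, cell) {
  as.integer((as.numeric(master) * 1000003 + as.numeric(stream) * 10007 +
                as.numeric(cell) * 101) %% 2147483647)
}

#' @noRd
stop_input <- function(...) stop(..., call. = FALSE)
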