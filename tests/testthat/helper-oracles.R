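# Independent brute-force oracles and small fixture builders, kept free of
# the package's own detection/aggregation code paths.

# Brute-force heatwave-day mask for one series: scan every [s, e] window
# and flag all days of any window of length >= min_duration whose days all
# exceed the threshold strictly. A window passes iff its exceedance count
# equals its length (checked in O(1) via a cumulative sum so the all-pairs
# scan stays fast on 400-day series).
brute_heatwave_days <- function(x, threshold, min_duration = 2L) {
  n <- length(x)
  exc <- x > threshold
  cs <- c(0L, cumsum(exc))
  flagged <- rep(FALSE, n)
  for (s in seq_len(n)) {
    e <- s:n
    len <- e - s + 1L
    ok <- (cs[e + 1L] - cs[s]) == len & len >= min_duration
    if (any(ok)) flagged[s:max(e[ok])] <- TRUE
  }
  flagged
}

# Brute-force trailing-window exposure: day d exposed iff any heatwave day
# in [d - window + 1, d] (truncated at the series start).
brute_exposure <- function(hw, window = 7L) {
  n <- length(hw)
  vapply(seq_len(n), function(d) any(hw[max(1L, d - window + 1L):d]),
         logical(1))
}

# A grid wrapping explicit per-cell series (rows) starting at a given date.
grid_from_series <- function(series, start = "2019-01-01",
                             scenario = "observed") {
  m <- if (is.matrix(series)) series else matrix(series, nrow = 1)
  temperature_grid(m, seq(as.Date(start), by = "day", length.out = ncol(m)),
                   scenario = scenario)
}

# Tiny demographic fixture with explicit values: one province per cell.
demo_fixture <- function(pop, birth_rate, ptb_rate, month_prop, years) {
  n_cells <- length(pop)
  demographic_tables(
    population = matrix(rep(pop, length(years)), n_cells),
    birth_rate = matrix(birth_rate, n_cells, length(years)),
    ptb_rate = matrix(ptb_rate, n_cells, length(years)),
    birth_month_prop = matrix(rep(month_prop, each = n_cells), n_cells),
    province_of_cell = seq_len(n_cells), years = years)
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_cells = 4L, n_provinces = 2L, years = 2015:2020,
         n_members = 2L, seed = 11L), list(...))
  do.call(climate_config, args)
}
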