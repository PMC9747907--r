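#' Configuration for the synthetic climate and demographic generator
#'
#' Bundles the parameters of the synthetic study system: a gridded region of
#' `n_cells` cells partitioned into `n_provinces` provinces, a daily tmax
#' climatology (annual sinusoid plus AR(1) Gaussian noise), and a factual /
#' counterfactual ensemble design in which an anthropogenic linear warming
#' trend is present only in the factual (and observed) series.
#'
#' Defaults mirror the study system the package models: a ten-member scenario
#' ensemble, a mid-latitude seasonal cycle peaking in mid-July, day-to-day
#' tmax noise with standard deviation 3 degC and lag-1 autocorrelation 0.7,
#' and an anthropogenic warming rate of 0.3 degC per decade. The spatial
#' extent (`n_cells`, `n_provinces`) and the year range are scale parameters
#' chosen per analysis.
#'
#' @param n_cells number of grid cells (>= `n_provinces`).
#' @param n_provinces number of provinces; cells are partitioned into
#'   provinces contiguously by index.
#' @param years integer vector of consecutive calendar years (inclusive).
#' @param temp_mean annual-mean tmax, degC.
#' @param temp_amplitude semi-amplitude of the annual sinusoid, degC.
#' @param peak_doy day-of-year at which the climatological tmax peaks.
#' @param noise_sd stationary standard deviation of daily noise, degC.
#' @param noise_autocorr lag-1 autocorrelation of the noise, in `[0, 1)`.
#' @param anthro_trend anthropogenic warming added to factual/observed
#'   series, degC per decade (linear ramp from the first day of the series).
#' @param n_members ensemble size per simulated scenario (>= 1).
#' @param seed master seed; all substreams derive from it deterministically.
#'
#' @return an object of class `climate_config` (a validated list).
#' @export
climate_config <- function(n_cells = 25L, n_provinces = 5L,
                           years = 2006:2020,
                           temp_mean = 18, temp_amplitude = 12,
                           peak_doy = 196L,
                           noise_sd = 3, noise_autocorr = 0.7,
                           anthro_trend = 0.3, n_members = 10L,
                           seed = 1L) {
  years <- as.integer(years)
  if (length(years) == 0L) stop_input("`years` must be non-empty")
  if (any(diff(years) != 1L)) stop_input("`years` must be consecutive")
  if (n_provinces < 1L || n_cells < n_provinces)
    stop_input("need n_cells >= n_provinces >= 1")
  if (noise_autocorr < 0 || noise_autocorr >= 1)
    stop_input("`noise_autocorr` must be in [0, 1)")
  if (n_members < 1L) stop_input("`n_members` must be >= 1")
  if (noise_sd < 0) stop_input("`noise_sd` must be >= 0")
  structure(
    list(n_cells = as.integer(n_cells), n_provinces = as.integer(n_provinces),
         years = years, temp_mean = temp_mean,
         temp_amplitude = temp_amplitude, peak_doy = as.integer(peak_doy),
         noise_sd = noise_sd, noise_autocorr = noise_autocorr,
         anthro_trend = anthro_trend, n_members = as.integer(n_members),
         seed = as.integer(seed)),
    class = "climate_config")
}

#' @export
print.climate_config <- function(x, ...) {
  cat("<climate_config> ", x$n_cells, " cells / ", x$n_provinces,
      " provinces, years ", min(x$years), "-", max(x$years),
      ", ", x$n_members, " members\n  climatology ", x$temp_mean, " +/- ",
      x$temp_amplitude, " degC, noise sd ", x$noise_sd, " (ar1 ",
      x$noise_autocorr, "), trend ", x$anthro_trend, " degC/decade, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

#' Read a climate configuration from a YAML or JSON file
#'
#' The file must contain keys matching the arguments of [climate_config()];
#' missing keys fall back to the defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a [climate_config()].
#' @export
read_climate_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$years) && length(raw$years) == 2L)
    raw$years <- raw$years[1]:raw$years[2]
  do.call(climate_config, raw[intersect(names(raw),
                                        names(formals(climate_config)))])
}

# Sinusoidal daily climatology for a date vector.
#' @noRd
seasonal_climatology <- function(config, dates) {
  doy <- as.integer(format(dates, "%j"))
  config$temp_mean + config$temp_amplitude *
    cos(2 * pi * (doy - config$peak_doy) / 365.25)
}

#' Generate a synthetic gridded daily tmax series
#'
#' Each cell's series is the sum of a shared sinusoidal climatology, cellwise
#' AR(1) Gaussian noise, and (for `factual` and `observed` scenarios) a
#' linear anthropogenic warming ramp of `anthro_trend` degC per decade. The
#' noise substream is derived from `(member, cell)` only, so the factual and
#' counterfactual members of the same index share natural variability
#' exactly and differ only by the trend; the observed series uses its own
#' stream, independent of every ensemble member.
#'
#' @param config a [climate_config()].
#' @param scenario `"observed"`, `"factual"` or `"counterfactual"`.
#' @param member ensemble member index in `1:n_members` (ignored for
#'   `"observed"`).
#' @return a [temperature_grid()]. Deterministic given
#'   `(config, scenario, member)`.
#' @examples
#' cfg <- climate_config(n_cells = 4, n_provinces = 2, years = 2018:2020,
#'                       n_members = 2)
#' g <- generate_temperature_grid(cfg, "factual", member = 1)
#' g
#' @export
generate_temperature_grid <- function(config, scenario = "observed",
                                      member = 1L) {
  stopifnot(inherits(config, "climate_config"))
  scenario <- match.arg(scenario,
                        c("observed", "factual", "counterfactual"))
  member <- as.integer(member)
  if (scenario != "observed" && (member < 1L || member > config$n_members))
    stop_input("`member` must be in 1:", config$n_members)

  dates <- seq(as.Date(sprintf("%d-01-01", min(config$years))),
               as.Date(sprintf("%d-12-31", max(config$years))), by = "day")
  n_days <- length(dates)
  clim <- seasonal_climatology(config, dates)
  # stream n_members + 1 is reserved for the observed series
  stream <- if (scenario == "observed") config$n_members + 1L else member

  a <- config$noise_autocorr
  innov_sd <- config$noise_sd * sqrt(1 - a^2)
  tmax <- matrix(0, config$n_cells, n_days)
  for (cell in seq_len(config$n_cells)) {
    set.seed(substream_seed(config$seed, stream, cell))
    z <- stats::rnorm(n_days)
    e <- numeric(n_days)
    e[1] <- z[1] * config$noise_sd
    if (n_days > 1)
      for (t in 2:n_days) e[t] <- a * e[t - 1] + innov_sd * z[t]
    tmax[cell, ] <- clim + e
  }
  if (scenario %in% c("observed", "factual")) {
    elapsed_decades <- as.numeric(dates - dates[1]) / 3652.5
    tmax <- sweep(tmax, 2, config$anthro_trend * elapsed_decades, `+`)
  }
  temperature_grid(tmax, dates, scenario = scenario, member = member)
}
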