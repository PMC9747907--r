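#' Province-level demographic tables with a gridded population
#'
#' Container for the baseline-birth inputs of the burden model: yearly
#' gridded population, province-level yearly birth rates and preterm-birth
#' (PTB) rates, province-level monthly live-birth proportions, and the
#' cell-to-province map. Province values apply uniformly to every cell of
#' the province.
#'
#' @param population numeric matrix, cells x years (persons, >= 0).
#' @param birth_rate numeric matrix, provinces x years (live births per
#'   person per year, in `[0, 1]`).
#' @param ptb_rate numeric matrix, provinces x years (fraction of live
#'   births delivered preterm, in `(0, 1)`).
#' @param birth_month_prop numeric matrix, provinces x 12; each row sums
#'   to 1 (fraction of the year's live births occurring in each month).
#' @param province_of_cell integer vector mapping each cell to a province.
#' @param years integer vector of the calendar years covered (columns).
#'
#' @return an object of class `demographic_tables`.
#' @seealso [generate_demographics()] for a synthetic instance,
#'   [baseline_ptb()] which consumes one.
#' @export
demographic_tables <- function(population, birth_rate, ptb_rate,
                               birth_month_prop, province_of_cell, years) {
  population <- as.matrix(population); birth_rate <- as.matrix(birth_rate)
  ptb_rate <- as.matrix(ptb_rate)
  birth_month_prop <- as.matrix(birth_month_prop)
  years <- as.integer(years)
  n_prov <- nrow(birth_rate)
  if (ncol(population) != length(years) || ncol(birth_rate) != length(years) ||
      ncol(ptb_rate) != length(years))
    stop_input("population/birth_rate/ptb_rate must have one column per year")
  if (nrow(ptb_rate) != n_prov || nrow(birth_month_prop) != n_prov)
    stop_input("province tables must agree on the number of provinces")
  if (ncol(birth_month_prop) != 12L)
    stop_input("`birth_month_prop` needs 12 monthly columns")
  if (length(province_of_cell) != nrow(population))
    stop_input("`province_of_cell` must map every population cell")
  if (!all(province_of_cell %in% seq_len(n_prov)))
    stop_input("`province_of_cell` refers to unknown provinces")
  if (any(population < 0)) stop_input("population must be >= 0")
  if (any(birth_rate < 0 | birth_rate > 1) || any(ptb_rate < 0 | ptb_rate > 1) ||
      any(birth_month_prop < 0 | birth_month_prop > 1))
    stop_input("rates and proportions must lie in [0, 1]")
  if (any(abs(rowSums(birth_month_prop) - 1) > 1e-9))
    stop_input("monthly birth proportions must sum to 1 per province")
  structure(
    list(population = population, birth_rate = birth_rate,
         ptb_rate = ptb_rate, birth_month_prop = birth_month_prop,
         province_of_cell = as.integer(province_of_cell), years = years),
    class = "demographic_tables")
}

#' @export
print.demographic_tables <- function(x, ...) {
  cat("<demographic_tables> ", nrow(x$population), " cells, ",
      nrow(x$birth_rate), " provinces, years ", min(x$years), "-",
      max(x$years), "\n  mean PTB rate ",
      sprintf("%.4f", mean(x$ptb_rate)), ", total population ",
      format(sum(x$population[, 1]), big.mark = ","), " (first year)\n",
      sep = "")
  invisible(x)
}

#' Generate internally consistent synthetic demographic tables
#'
#' Population is log-uniform across cells and grows slowly over years; birth
#' rates vary by province around a national level of about 11 per 1,000; PTB
#' rates start from province-specific perturbations of `base_ptb_rate` and
#' grow geometrically by `ptb_growth` per year (default 1.3%/yr, the
#' national trend the baseline model assumes); monthly birth proportions are
#' drawn from a Dirichlet-like scheme (normalized Gamma variates around a
#' mild seasonal shape) and renormalized to sum to exactly 1. Provinces
#' partition cells contiguously by index.
#'
#' @param config a [climate_config()] (supplies cells, provinces, years,
#'   seed).
#' @param base_ptb_rate national PTB prevalence in the first year, in
#'   `(0, 1)`.
#' @param ptb_growth annual multiplicative growth of the PTB rate.
#' @return a [demographic_tables()]. Deterministic given `config`.
#' @examples
#' demo <- generate_demographics(climate_config(n_cells = 4, n_provinces = 2,
#'                                              years = 2018:2020))
#' rowSums(demo$birth_month_prop)
#' @export
generate_demographics <- function(config, base_ptb_rate = 0.07,
                                  ptb_growth = 1.013) {
  stopifnot(inherits(config, "climate_config"))
  if (base_ptb_rate <= 0 || base_ptb_rate >= 1)
    stop_input("`base_ptb_rate` must be in (0, 1)")
  n_years <- length(config$years)
  # province perturbations stay below ~1.3x base; bound the final-year rate
  if (base_ptb_rate * 1.3 * ptb_growth^(n_years - 1) >= 1)
    stop_input("`ptb_growth` drives PTB rates to 1 or above over the range")

  set.seed(substream_seed(config$seed, 0L, 0L))
  n_cells <- config$n_cells; n_prov <- config$n_provinces

  population <- matrix(0, n_cells, n_years)
  pop0 <- exp(stats::runif(n_cells, log(5e4), log(2e6)))
  for (j in seq_len(n_years))
    population[, j] <- round(pop0 * 1.004^(j - 1))

  birth_rate <- matrix(rep(stats::runif(n_prov, 0.009, 0.013), n_years),
                       n_prov, n_years)

  prov_base <- base_ptb_rate * stats::runif(n_prov, 0.8, 1.3)
  ptb_rate <- outer(prov_base, ptb_growth^(seq_len(n_years) - 1))

  # mild birth seasonality (more autumn births), Dirichlet-like jitter
  shape <- 40 * (1 + 0.2 * cos(2 * pi * ((1:12) - 10) / 12))
  birth_month_prop <- t(vapply(seq_len(n_prov), function(p) {
    g <- stats::rgamma(12, shape = shape)
    g / sum(g)
  }, numeric(12)))

  province_of_cell <- sort(rep_len(seq_len(n_prov), n_cells))
  demographic_tables(population, birth_rate, ptb_rate, birth_month_prop,
                     province_of_cell, config$years)
}

#' Write demographic tables as CSV files
#'
#' One file per table is written under `dir`: `population.csv` (cell, year,
#' population), `birth_rate.csv` and `ptb_rate.csv` (province, year, value),
#' `birth_month_prop.csv` (province, month, proportion) and
#' `province_of_cell.csv` (cell, province).
#'
#' @param demo a [demographic_tables()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_demographic_tables <- function(demo, dir) {
  stopifnot(inherits(demo, "demographic_tables"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- function(m, rows, rowname, cols, colname, value) {
    df <- data.frame(rep(rows, times = length(cols)),
                     rep(cols, each = length(rows)), as.vector(m))
    names(df) <- c(rowname, colname, value)
    df
  }
  utils::write.csv(long(demo$population, seq_len(nrow(demo$population)),
                        "cell", demo$years, "year", "population"),
                   file.path(dir, "population.csv"), row.names = FALSE)
  utils::write.csv(long(demo$birth_rate, seq_len(nrow(demo$birth_rate)),
                        "province", demo$years, "year", "birth_rate"),
                   file.path(dir, "birth_rate.csv"), row.names = FALSE)
  utils::write.csv(long(demo$ptb_rate, seq_len(nrow(demo$ptb_rate)),
                        "province", demo$years, "year", "ptb_rate"),
                   file.path(dir, "ptb_rate.csv"), row.names = FALSE)
  utils::write.csv(long(demo$birth_month_prop,
                        seq_len(nrow(demo$birth_month_prop)), "province",
                        1:12, "month", "proportion"),
                   file.path(dir, "birth_month_prop.csv"), row.names = FALSE)
  utils::write.csv(data.frame(cell = seq_along(demo$province_of_cell),
                              province = demo$province_of_cell),
                   file.path(dir, "province_of_cell.csv"), row.names = FALSE)
  invisible(dir)
}
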