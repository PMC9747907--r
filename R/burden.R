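#' Exposure-response risk model for last-week heatwave exposure
#'
#' Holds the relative risk (RR) of preterm delivery given at least one
#' heatwave day in the final gestational week, with its 95% confidence
#' interval. The default RR of 1.19 (95% CI 1.09-1.29) is the national
#' estimate from an extended Cox model on a Chinese birth cohort; the RR is
#' an input to this package, not something it estimates. The attributable
#' fraction among the exposed is `(RR - 1) / RR`.
#'
#' @param rr relative risk point estimate (> 0).
#' @param ci length-2 numeric, the 95% CI `(low, high)` with
#'   `low <= rr <= high` and `low > 0`.
#' @return an object of class `risk_model`.
#' @export
risk_model <- function(rr = 1.19, ci = c(1.09, 1.29)) {
  if (!is.numeric(rr) || length(rr) != 1L || rr <= 0)
    stop_input("`rr` must be a single positive number")
  if (length(ci) != 2L || ci[1] <= 0 || ci[1] > rr || ci[2] < rr)
    stop_input("`ci` must satisfy 0 < low <= rr <= high")
  structure(list(rr = rr, ci = as.numeric(ci)), class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> RR %.3f (95%% CI %.3f-%.3f), AF among exposed %.4f\n",
              x$rr, x$ci[1], x$ci[2], (x$rr - 1) / x$rr))
  invisible(x)
}

#' Attributable fraction for exposed and unexposed days
#'
#' Returns `(RR - 1) / RR` where `exposed` is `TRUE` and 0 where it is
#' `FALSE`: unexposed delivery days carry no heatwave-attributable burden.
#'
#' @param risk a [risk_model()] or a positive RR value.
#' @param exposed logical vector/matrix of exposure indicators.
#' @return numeric of the same shape as `exposed`.
#' @examples
#' attributable_fraction(risk_model(1.19), c(TRUE, FALSE))
#' @export
attributable_fraction <- function(risk, exposed) {
  rr <- if (inherits(risk, "risk_model")) risk$rr else risk
  if (!is.numeric(rr) || rr <= 0) stop_input("RR must be positive")
  af <- (rr - 1) / rr
  out <- ifelse(exposed, af, 0)
  if (is.matrix(exposed)) out <- matrix(out, nrow(exposed), ncol(exposed))
  out
}

#' Daily baseline preterm births per grid cell
#'
#' The expected (no-heatwave-information) PTB count for cell g in
#' warm-season month m of year y is the four-factor product
#' `Pop[g,y] * BirthRate[g,y] * PTBrate[g,y] * BirthMon[g,m]`, with
#' province values applied uniformly to member cells. The monthly count is
#' spread evenly over the month's calendar days to give the daily baseline.
#' Days outside the warm season carry a zero baseline: the burden model
#' only accrues attributable cases on warm-season delivery days.
#'
#' @param demo a [demographic_tables()].
#' @param years analysis years (subset of `demo$years`; default all).
#' @param warm_months warm-season months (default `5:10`).
#' @return an object of class `baseline_ptb_field`: `daily` (cells x days
#'   matrix), `monthly` (cells x 12 x years array, zero outside the warm
#'   season), `dates`, `years`, `warm_months`, `province_of_cell`,
#'   `births_annual` (named national live births per year) and
#'   `warm_base_annual` (national warm-season baseline PTBs per year).
#' @export
baseline_ptb <- function(demo, years = NULL, warm_months = 5:10) {
  stopifnot(inherits(demo, "demographic_tables"))
  years <- as.integer(years %||% demo$years)
  if (!all(years %in% demo$years))
    stop_input("demographic tables do not cover the requested years")
  if (!all(warm_months %in% 1:12) || length(warm_months) == 0L)
    stop_input("`warm_months` must be a non-empty subset of 1:12")

  prov <- demo$province_of_cell
  n_cells <- nrow(demo$population)
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  mon <- date_month(dates); yr <- date_year(dates)

  monthly <- array(0, c(n_cells, 12L, length(years)))
  daily <- matrix(0, n_cells, length(dates))
  for (j in seq_along(years)) {
    y <- years[j]; jy <- match(y, demo$years)
    annual <- demo$population[, jy] * demo$birth_rate[prov, jy] *
      demo$ptb_rate[prov, jy]
    for (m in warm_months) {
      monthly[, m, j] <- annual * demo$birth_month_prop[prov, m]
      idx <- yr == y & mon == m
      daily[, idx] <- monthly[, m, j] / days_in_month(y, m)
    }
  }

  births_prov <- vapply(seq_along(years), function(j) {
    jy <- match(years[j], demo$years)
    as.numeric(rowsum(demo$population[, jy] * demo$birth_rate[prov, jy],
                      prov))
  }, numeric(nrow(demo$birth_rate)))
  births_prov <- matrix(births_prov, nrow = nrow(demo$birth_rate),
                        dimnames = list(NULL, years))

  structure(
    list(daily = daily, monthly = monthly, dates = dates, years = years,
         warm_months = warm_months, province_of_cell = prov,
         births_annual = colSums(births_prov),
         births_annual_prov = births_prov,
         warm_base_annual = vapply(seq_along(years), function(j)
           sum(monthly[, , j]), numeric(1)) |> stats::setNames(years)),
    class = "baseline_ptb_field")
}

#' Heatwave-attributable preterm births
#'
#' Multiplies the daily baseline PTB field by the attributable fraction,
#' which is `(RR - 1)/RR` on exposed cell-days and 0 otherwise, and
#' aggregates to annual national and provincial totals, attributable PTBs
#' per million live births, and the share of warm-season baseline PTBs.
#'
#' @param base a [baseline_ptb_field()] from [baseline_ptb()].
#' @param exposure an `exposure_field` from [exposure_window()] on the same
#'   cells; its dates must cover the baseline dates.
#' @param risk a [risk_model()].
#' @param scenario label stored in the result (default taken from exposure).
#' @param member ensemble member index stored in the result.
#' @return an object of class `burden_result`: `aptb_daily` (cells x days),
#'   `annual` (named national totals per year), `annual_prov` (province x
#'   year matrix), `per_million`, `share_pct`, `exposed_base_annual` (the
#'   baseline PTBs on exposed warm-season days, the sufficient statistic
#'   for rescaling under alternative RR draws), `af`, `scenario`, `member`.
#' @export
attributable_ptb <- function(base, exposure, risk,
                             scenario = "observed", member = 1L) {
  stopifnot(inherits(base, "baseline_ptb_field"),
            inherits(exposure, "exposure_field"),
            inherits(risk, "risk_model"))
  if (nrow(base$daily) != nrow(exposure$exposed))
    stop_input("baseline and exposure fields have different cell counts")
  idx <- match(base$dates, exposure$dates)
  if (anyNA(idx))
    stop_input("exposure field does not cover the baseline date range")
  exposed <- exposure$exposed[, idx, drop = FALSE]

  af <- (risk$rr - 1) / risk$rr
  aptb <- base$daily * af * exposed

  yr <- date_year(base$dates)
  years <- base$years
  annual <- vapply(years, function(y)
    sum(aptb[, yr == y, drop = FALSE]), numeric(1))
  names(annual) <- years
  exposed_base <- vapply(years, function(y)
    sum(base$daily[, yr == y, drop = FALSE] *
          exposed[, yr == y, drop = FALSE]), numeric(1))
  names(exposed_base) <- years

  prov <- base$province_of_cell
  annual_prov <- vapply(years, function(y)
    as.numeric(rowsum(rowSums(aptb[, yr == y, drop = FALSE]), prov)),
    numeric(length(unique(prov))))
  annual_prov <- matrix(annual_prov, nrow = length(unique(prov)),
                        dimnames = list(sort(unique(prov)), years))

  structure(
    list(aptb_daily = aptb, annual = annual, annual_prov = annual_prov,
         per_million = annual / base$births_annual * 1e6,
         share_pct = annual / base$warm_base_annual * 100,
         exposed_base_annual = exposed_base, af = af,
         scenario = scenario, member = as.integer(member)),
    class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat("<burden_result> scenario ", x$scenario, " (member ", x$member,
      "), years ", names(x$annual)[1], "-",
      names(x$annual)[length(x$annual)], "\n", sep = "")
  cat(sprintf("  mean annual aPTB %.2f (%.1f per million births, %.2f%% of warm-season PTBs)\n",
              mean(x$annual), mean(x$per_million), mean(x$share_pct)))
  invisible(x)
}

#' Summarize a burden result as a tidy table
#'
#' @param result a `burden_result`.
#' @return data.frame with columns `scenario`, `member`, `year`, `aptb`,
#'   `per_million`, `share_pct`.
#' @export
burden_table <- function(result) {
  stopifnot(inherits(result, "burden_result"))
  data.frame(scenario = result$scenario, member = result$member,
             year = as.integer(names(result$annual)),
             aptb = unname(result$annual),
             per_million = unname(result$per_million),
             share_pct = unname(result$share_pct))
}

#' Factual-minus-counterfactual scenario comparison
#'
#' Pairs factual and counterfactual burden results member-by-member
#' (same climate model), differences their annual attributable PTBs to
#' obtain the anthropogenic contribution, and summarizes over the
#' ensemble. The anthropogenic proportion is computed on ensemble means of
#' numerator and denominator (not the mean of per-member ratios), which is
#' stable when individual members have near-zero factual burden; it is
#' reported as `NA` for years with zero ensemble-mean factual burden.
#'
#' @param factual list of `burden_result` (one per ensemble member).
#' @param counterfactual list of `burden_result`, paired by position with
#'   `factual`.
#' @return an object of class `scenario_comparison`: member x year
#'   matrices `factual`, `counterfactual`, `anthropogenic`; ensemble-mean
#'   vectors `factual_mean`, `counterfactual_mean`, `anthropogenic_mean`,
#'   `proportion_pct` per year; and scalars `mean_annual_factual`,
#'   `mean_annual_anthropogenic`, `overall_proportion_pct` (total
#'   anthropogenic over total factual burden across all years).
#' @export
scenario_difference <- function(factual, counterfactual) {
  if (inherits(factual, "burden_result")) factual <- list(factual)
  if (inherits(counterfactual, "burden_result"))
    counterfactual <- list(counterfactual)
  if (length(factual) != length(counterfactual) || length(factual) == 0L)
    stop_input("factual and counterfactual ensembles must pair member-wise")
  yrs <- names(factual[[1]]$annual)
  for (b in c(factual, counterfactual))
    if (!identical(names(b$annual), yrs))
      stop_input("all members must cover the same years")

  fm <- do.call(rbind, lapply(factual, function(b) b$annual))
  cm <- do.call(rbind, lapply(counterfactual, function(b) b$annual))
  an <- fm - cm
  f_mean <- colMeans(fm); c_mean <- colMeans(cm); a_mean <- colMeans(an)
  prop <- ifelse(f_mean > 0, a_mean / f_mean * 100, NA_real_)
  structure(
    list(factual = fm, counterfactual = cm, anthropogenic = an,
         factual_mean = f_mean, counterfactual_mean = c_mean,
         anthropogenic_mean = a_mean, proportion_pct = prop,
         mean_annual_factual = mean(f_mean),
         mean_annual_anthropogenic = mean(a_mean),
         overall_proportion_pct =
           if (sum(f_mean) > 0) sum(a_mean) / sum(f_mean) * 100 else NA_real_,
         n_members = length(factual)),
    class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("<scenario_comparison> ", x$n_members, " paired members, years ",
      names(x$factual_mean)[1], "-",
      names(x$factual_mean)[length(x$factual_mean)], "\n", sep = "")
  cat(sprintf("  mean annual aPTB: factual %.2f, anthropogenic %.2f (%.1f%% of factual)\n",
              x$mean_annual_factual, x$mean_annual_anthropogenic,
              x$overall_proportion_pct))
  invisible(x)
}
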