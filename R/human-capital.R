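#' Incidence of a downstream outcome among preterm births
#'
#' Children born preterm face elevated risks of later-life outcomes (e.g.
#' neonatal death, asthma, diabetes, ASD, ADHD). Given the outcome's
#' whole-population prevalence `p_outcome`, the national PTB rate `p_ptb`
#' and the outcome's relative risk in the preterm group `rr_outcome`
#' (= I_e / I_0), the prevalence decomposes as
#' `p_outcome = p_ptb * I_e + (1 - p_ptb) * I_e / rr_outcome`, which
#' inverts to
#' `I_e = p_outcome * rr_outcome / (p_ptb * rr_outcome + 1 - p_ptb)`.
#'
#' @param rr_outcome relative risk of the outcome given preterm birth (> 0).
#' @param p_outcome whole-population prevalence of the outcome, in `(0, 1)`.
#' @param p_ptb national PTB rate, in `(0, 1)`.
#' @return list with `i_e` (incidence among preterm births) and `i_0`
#'   (incidence among term births, `i_e / rr_outcome`). Vectorized over
#'   `rr_outcome` / `p_outcome`.
#' @examples
#' incidence_in_ptb(2, 0.01, 0.07)$i_e  # 0.02/1.07
#' @export
incidence_in_ptb <- function(rr_outcome, p_outcome, p_ptb) {
  if (any(rr_outcome <= 0)) stop_input("`rr_outcome` must be positive")
  if (any(p_outcome <= 0 | p_outcome >= 1))
    stop_input("`p_outcome` must be in (0, 1)")
  if (any(p_ptb <= 0 | p_ptb >= 1)) stop_input("`p_ptb` must be in (0, 1)")
  i_e <- p_outcome * rr_outcome / (p_ptb * rr_outcome + 1 - p_ptb)
  if (any(i_e < 0 | i_e > 1))
    stop_input("inconsistent inputs: implied incidence outside [0, 1]")
  list(i_e = i_e, i_0 = i_e / rr_outcome)
}

#' Additional outcome cases caused by heatwave-attributable preterm births
#'
#' `N_add = nPTB * (I_e - P_outcome)`: each attributable PTB contributes
#' the excess of the preterm-group incidence over the population
#' prevalence. Exactly linear in `nptb`.
#'
#' @param nptb annual heatwave-attributable PTB count (>= 0); may be a
#'   vector (e.g. point, lo, hi).
#' @inheritParams incidence_in_ptb
#' @return numeric additional cases, same length as `nptb`.
#' @export
additional_cases <- function(nptb, rr_outcome, p_outcome, p_ptb) {
  if (any(nptb < 0)) stop_input("`nptb` must be >= 0")
  inc <- incidence_in_ptb(rr_outcome, p_outcome, p_ptb)
  nptb * (inc$i_e - p_outcome)
}

#' Total IQ points lost to heatwave-attributable preterm births
#'
#' @param nptb annual attributable PTB count (>= 0).
#' @param iq_points_per_ptb IQ points lost per preterm child (>= 0).
#' @return `nptb * iq_points_per_ptb`.
#' @export
iq_loss <- function(nptb, iq_points_per_ptb) {
  if (any(nptb < 0) || any(iq_points_per_ptb < 0))
    stop_input("inputs must be >= 0")
  nptb * iq_points_per_ptb
}

#' Read an outcome-specification table
#'
#' Columns: `name`, `dimension` (health / cognition / non-cognition),
#' `rr_outcome`, `p_outcome`, `iq_points_per_ptb` (set, with `countable =
#' FALSE`, only for the reduced-IQ row), `unit_cost` (per case, or per IQ
#' point for the IQ row; millions of USD), `currency_year`,
#' `include_in_total`, `countable`.
#'
#' The packaged default (`outcome_specs_synthetic.csv`) is a synthetic
#' placeholder panel with the study's outcome structure but invented
#' parameter values; analyses of real data must substitute evidence-based
#' RRs, prevalences and unit costs.
#'
#' @param path CSV path; default the packaged synthetic panel.
#' @return validated data.frame of class `outcome_specs`.
#' @export
read_outcome_specs <- function(path = NULL) {
  path <- path %||% system.file("extdata", "outcome_specs_synthetic.csv",
                                package = "heatptb", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("name", "dimension", "rr_outcome", "p_outcome",
              "iq_points_per_ptb", "unit_cost", "currency_year",
              "include_in_total", "countable")
  if (!all(needed %in% names(df)))
    stop_input("outcome-spec file must have columns: ",
               paste(needed, collapse = ", "))
  df$include_in_total <- as.logical(df$include_in_total)
  df$countable <- as.logical(df$countable)
  with(df[df$countable, ], {
    if (any(rr_outcome <= 0, na.rm = TRUE))
      stop_input("countable outcomes need rr_outcome > 0")
    if (any(p_outcome <= 0 | p_outcome >= 1, na.rm = TRUE))
      stop_input("countable outcomes need p_outcome in (0, 1)")
  })
  if (any(df$unit_cost < 0, na.rm = TRUE))
    stop_input("unit costs must be >= 0")
  class(df) <- c("outcome_specs", "data.frame")
  df
}

#' Human-capital consequences of attributable preterm births
#'
#' Converts an annual attributable-PTB count into additional cases of each
#' countable outcome, total IQ points lost, and monetized costs. Countable
#' outcomes use `N_add = nPTB * (I_e - P_outcome)`; the reduced-IQ row uses
#' `nPTB * iq_points_per_ptb`. Costs are `N * unit_cost`; the direct PTB
#' cost is `nPTB * unit_cost_ptb`; the total human-capital cost sums the
#' per-outcome costs flagged `include_in_total` (neonatal death is
#' conventionally excluded, as is the direct PTB cost). When `nptb` has
#' several elements (point, lo, hi) each column of the result carries the
#' corresponding bound, scaled through the same linear formulas.
#'
#' @param nptb annual attributable PTB count; optionally a named vector
#'   `c(point, lo, hi)` whose extra elements populate `n_lo` / `n_hi`.
#' @param specs an `outcome_specs` table (see [read_outcome_specs()]).
#' @param p_ptb national PTB rate in `(0, 1)`.
#' @param unit_cost_ptb direct cost per PTB case (millions of USD; default 0
#'   skips the direct-cost line).
#' @return data.frame of class `human_capital_result`: per outcome `name`,
#'   `dimension`, `n` (cases or IQ points), `n_lo`, `n_hi`, `cost`
#'   (millions USD), `include_in_total`, `currency_year`; attributes
#'   `nptb`, `p_ptb`, `direct_ptb_cost`, `total_human_capital_cost`,
#'   `mixed_currency_years`.
#' @export
human_capital <- function(nptb, specs, p_ptb, unit_cost_ptb = 0) {
  stopifnot(inherits(specs, "data.frame"))
  if (unit_cost_ptb < 0) stop_input("`unit_cost_ptb` must be >= 0")
  point <- nptb[1]
  lo <- if (length(nptb) >= 2) nptb[2] else NA_real_
  hi <- if (length(nptb) >= 3) nptb[3] else NA_real_

  n_for <- function(x) {
    vapply(seq_len(nrow(specs)), function(i) {
      if (is.na(x)) return(NA_real_)
      if (isTRUE(specs$countable[i])) {
        additional_cases(x, specs$rr_outcome[i], specs$p_outcome[i], p_ptb)
      } else {
        iq_loss(x, specs$iq_points_per_ptb[i])
      }
    }, numeric(1))
  }
  n <- n_for(point)
  out <- data.frame(name = specs$name, dimension = specs$dimension,
                    n = n, n_lo = n_for(lo), n_hi = n_for(hi),
                    cost = n * specs$unit_cost,
                    include_in_total = specs$include_in_total,
                    currency_year = specs$currency_year)
  attr(out, "nptb") <- unname(point)
  attr(out, "p_ptb") <- p_ptb
  attr(out, "direct_ptb_cost") <- unname(point * unit_cost_ptb)
  attr(out, "total_human_capital_cost") <- total_human_capital_cost(out)
  attr(out, "mixed_currency_years") <-
    length(unique(specs$currency_year[specs$include_in_total])) > 1L
  class(out) <- c("human_capital_result", "data.frame")
  out
}

#' Sum the per-outcome costs included in the human-capital total
#'
#' Sums the `cost` column over rows flagged `include_in_total`. The same
#' summation applies to any table with those two columns, including
#' externally supplied reference tables of printed per-outcome costs.
#'
#' @param result a `human_capital_result`, or any data.frame with numeric
#'   `cost` (or `cost_musd`) and logical `include_in_total` columns.
#' @return numeric total (millions of USD).
#' @export
total_human_capital_cost <- function(result) {
  cost <- result[["cost"]] %||% result[["cost_musd"]]
  if (is.null(cost) || is.null(result[["include_in_total"]]))
    stop_input("need `cost` (or `cost_musd`) and `include_in_total` columns")
  sum(cost[as.logical(result$include_in_total)], na.rm = TRUE)
}

#' @export
print.human_capital_result <- function(x, ...) {
  cat("<human_capital_result> nPTB =", format(attr(x, "nptb")), "\n")
  print.data.frame(x, digits = 4)
  cat(sprintf("direct PTB cost %.1f; total human-capital cost %.1f (millions USD)\n",
              attr(x, "direct_ptb_cost"), attr(x, "total_human_capital_cost")))
  invisible(x)
}

#' Published reference table of human-capital losses
#'
#' The published human-capital loss table for heatwave-attributable
#' preterm births in China (2010-2020 annual averages): per-outcome case
#' counts with 95% CIs and monetized costs in millions of 2015 USD (two
#' rows in 2014 USD), for the actual-climate and anthropogenic-climate-
#' change scenarios. Used as an arithmetic reference for the cost-summation
#' machinery; the direct-aPTB and neonatal-death rows are excluded from
#' the human-capital total.
#'
#' @return data.frame with columns `scenario`, `outcome`, `dimension`,
#'   `n_point`, `n_lo`, `n_hi`, `cost_musd`, `include_in_total`.
#' @export
human_capital_reference <- function() {
  path <- system.file("extdata", "china_human_capital_reference.csv",
                      package = "heatptb", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$include_in_total <- as.logical(df$include_in_total)
  df
}
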