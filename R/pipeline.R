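#' Assemble a full pipeline run configuration
#'
#' A single configuration object drives the end-to-end analysis:
#' synthetic-climate parameters, analysis years, heatwave definition,
#' exposure window, risk model, Monte Carlo settings and demographic
#' parameters.
#'
#' @param climate a [climate_config()].
#' @param years analysis years for the burden stage (subset of the climate
#'   years; default the last 11 climate years, mirroring a decade-scale
#'   attribution window).
#' @param warm_months warm-season months (default `5:10`).
#' @param percentile heatwave threshold percentile (default 0.9).
#' @param min_duration minimum heatwave run length (default 2 days).
#' @param window_days exposure window (default 7, the final gestational
#'   week).
#' @param risk a [risk_model()].
#' @param mc an [mc_spec()].
#' @param base_ptb_rate first-year national PTB rate for the synthetic
#'   demographics.
#' @param ptb_growth annual multiplicative PTB-rate growth (default 1.013).
#' @param outcome_specs_path optional path to an outcome-spec CSV; default
#'   the packaged synthetic panel.
#' @param unit_cost_ptb direct cost per PTB case, millions USD.
#' @return an object of class `run_config`.
#' @export
run_config <- function(climate = climate_config(),
                       years = NULL,
                       warm_months = 5:10, percentile = 0.9,
                       min_duration = 2L, window_days = 7L,
                       risk = risk_model(), mc = mc_spec(),
                       base_ptb_rate = 0.07, ptb_growth = 1.013,
                       outcome_specs_path = NULL, unit_cost_ptb = 0.0701) {
  stopifnot(inherits(climate, "climate_config"),
            inherits(risk, "risk_model"), inherits(mc, "mc_spec"))
  years <- as.integer(years %||% utils::tail(climate$years, 11))
  if (!all(years %in% climate$years))
    stop_input("analysis `years` must lie inside the climate years")
  structure(list(climate = climate, years = years,
                 warm_months = warm_months, percentile = percentile,
                 min_duration = as.integer(min_duration),
                 window_days = as.integer(window_days),
                 risk = risk, mc = mc, base_ptb_rate = base_ptb_rate,
                 ptb_growth = ptb_growth,
                 outcome_specs_path = outcome_specs_path,
                 unit_cost_ptb = unit_cost_ptb),
            class = "run_config")
}

# Detection + burden for one temperature grid against fixed thresholds.
#' @noRd
burden_for_grid <- function(grid, thresholds, base, config) {
  mask <- detect_heatwaves(grid, thresholds, config$min_duration)
  expo <- exposure_window(mask, config$window_days)
  attributable_ptb(base, expo, config$risk,
                   scenario = grid$scenario, member = grid$member)
}

#' Run the full attribution pipeline on synthetic data
#'
#' Stages: (1) generate the observed series, the factual and counterfactual
#' ensembles, and demographic tables; (2) bias-correct each simulated member
#' against the observed series by quantile mapping, fitting the map on the
#' factual member and applying the identical map to its paired
#' counterfactual member; (3) compute per-cell heatwave thresholds — from
#' the observed series for the observed burden, and from each member's
#' bias-corrected factual series for both of that member's scenarios, so a
#' scenario-specific threshold cannot erase the attribution signal; (4)
#' detect heatwaves, build last-week exposure, and accumulate attributable
#' PTBs over warm-season days; (5) difference the scenarios to isolate the
#' anthropogenic contribution; (6) propagate RR uncertainty by Monte Carlo;
#' (7) cascade the mean annual burden into human-capital losses.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, stage outputs are written
#'   as CSV (`heatwave_days.csv`, `burden.csv`, `scenario_comparison.csv`,
#'   `burden_ci.csv`, `human_capital.csv`) plus a `manifest.yaml` recording
#'   the configuration, seeds and file checksums.
#' @param verbose print stage-level progress with cell/member counts.
#' @return list with elements `demo`, `thresholds_observed`, `observed`
#'   (burden_result), `factual`, `counterfactual` (lists of burden_result),
#'   `comparison` (scenario_comparison), `ci_observed`, `ci_anthropogenic`
#'   (data.frames), `human_capital`, `heatwave_days`, `config`.
#' @examples
#' \donttest{
#' cfg <- run_config(climate = climate_config(n_cells = 4, n_provinces = 2,
#'                                            years = 2015:2020,
#'                                            n_members = 2, seed = 7),
#'                   years = 2015:2020, mc = mc_spec(n_draws = 200, seed = 7))
#' res <- run_pipeline(cfg)
#' res$comparison
#' }
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(...)
  cc <- config$climate

  say("stage 1/7 synthetic data: ", cc$n_cells, " cells, ",
      cc$n_members, " members")
  observed_grid <- generate_temperature_grid(cc, "observed")
  demo <- generate_demographics(cc, config$base_ptb_rate, config$ptb_growth)
  base <- baseline_ptb(demo, config$years, config$warm_months)

  say("stage 2/7 burden in actual climate")
  thr_obs <- compute_threshold(observed_grid, config$warm_months,
                               config$percentile)
  mask_obs <- detect_heatwaves(observed_grid, thr_obs, config$min_duration)
  hwd <- heatwave_days_by_year(mask_obs)
  observed <- attributable_ptb(
    base, exposure_window(mask_obs, config$window_days), config$risk,
    scenario = "observed")

  say("stage 3-4/7 bias correction + scenario burdens, ",
      cc$n_members, " members")
  factual <- vector("list", cc$n_members)
  counterfactual <- vector("list", cc$n_members)
  for (m in seq_len(cc$n_members)) {
    fg <- generate_temperature_grid(cc, "factual", m)
    cg <- generate_temperature_grid(cc, "counterfactual", m)
    bc <- fit_bias_correction(fg, observed_grid)
    fg_bc <- apply_bias_correction(fg, bc)
    cg_bc <- apply_bias_correction(cg, bc)
    thr <- compute_threshold(fg_bc, config$warm_months, config$percentile)
    factual[[m]] <- burden_for_grid(fg_bc, thr, base, config)
    counterfactual[[m]] <- burden_for_grid(cg_bc, thr, base, config)
    factual[[m]]$scenario <- "factual"; factual[[m]]$member <- m
    counterfactual[[m]]$scenario <- "counterfactual"
    counterfactual[[m]]$member <- m
  }

  say("stage 5/7 scenario differencing")
  comparison <- scenario_difference(factual, counterfactual)

  say("stage 6/7 Monte Carlo uncertainty, ", config$mc$n_draws, " draws")
  ci_observed <- burden_ci(observed, config$risk, config$mc)
  draws <- sample_rr(config$risk, config$mc)
  anthro_draws <- lapply(seq_len(cc$n_members), function(m)
    burden_draws(factual[[m]], draws) -
      burden_draws(counterfactual[[m]], draws))
  anthro_mean_flat <- unlist(lapply(anthro_draws, rowMeans))
  ci_anthro <- data.frame(
    quantity = "mean_annual_anthropogenic",
    point = comparison$mean_annual_anthropogenic,
    lo = empirical_ci(anthro_mean_flat)[["lo"]],
    hi = empirical_ci(anthro_mean_flat)[["hi"]],
    n_draws = config$mc$n_draws, n_models = cc$n_members)

  say("stage 7/7 human-capital cascade")
  specs <- read_outcome_specs(config$outcome_specs_path)
  p_ptb <- mean(demo$ptb_rate)
  hc <- human_capital(
    c(mean(observed$annual), ci_observed[ci_observed$quantity ==
        "mean_annual", "lo"], ci_observed[ci_observed$quantity ==
        "mean_annual", "hi"]),
    specs, p_ptb, config$unit_cost_ptb)

  result <- list(demo = demo, thresholds_observed = thr_obs,
                 observed = observed, factual = factual,
                 counterfactual = counterfactual, comparison = comparison,
                 ci_observed = ci_observed, ci_anthropogenic = ci_anthro,
                 human_capital = hc, heatwave_days = hwd, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# Serialize pipeline outputs and a reproducibility manifest.
#' @noRd
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  hwd <- result$heatwave_days
  files <- c(
    w(data.frame(year = as.integer(colnames(hwd$by_cell_year)),
                 national_mean_hwd = unname(hwd$national)),
      "heatwave_days.csv"),
    w(do.call(rbind, c(list(burden_table(result$observed)),
                       lapply(result$factual, burden_table),
                       lapply(result$counterfactual, burden_table))),
      "burden.csv"),
    w(data.frame(year = as.integer(names(result$comparison$factual_mean)),
                 factual = unname(result$comparison$factual_mean),
                 counterfactual =
                   unname(result$comparison$counterfactual_mean),
                 anthropogenic =
                   unname(result$comparison$anthropogenic_mean),
                 proportion_pct = unname(result$comparison$proportion_pct)),
      "scenario_comparison.csv"),
    w(rbind(cbind(result$ci_observed, scenario = "observed"),
            cbind(result$ci_anthropogenic, scenario = "anthropogenic")),
      "burden_ci.csv"),
    w(as.data.frame(result$human_capital), "human_capital.csv"))
  cc <- result$config$climate
  manifest <- list(
    package_version = as.character(utils::packageVersion("heatptb")),
    seed = cc$seed, mc_seed = result$config$mc$seed,
    config = list(
      n_cells = cc$n_cells, n_provinces = cc$n_provinces,
      years = range(cc$years), analysis_years = range(result$config$years),
      n_members = cc$n_members, anthro_trend = cc$anthro_trend,
      percentile = result$config$percentile,
      min_duration = result$config$min_duration,
      window_days = result$config$window_days,
      rr = result$config$risk$rr, rr_ci = result$config$risk$ci,
      n_draws = result$config$mc$n_draws),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
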