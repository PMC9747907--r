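#' Monte Carlo specification for risk-coefficient uncertainty
#'
#' The burden model depends on a single exposure coefficient, ln(RR), so
#' the multivariate-normal sampling of model coefficients collapses to a
#' univariate normal on the log relative risk. Its standard deviation is
#' recovered from the printed 95% CI as
#' `(ln hi - ln lo) / (2 * qnorm(0.975))`.
#'
#' @param n_draws number of coefficient samples (default 1000).
#' @param seed integer seed making the draws reproducible.
#' @return an object of class `mc_spec`.
#' @export
mc_spec <- function(n_draws = 1000L, seed = 1L) {
  n_draws <- as.integer(n_draws)
  if (n_draws < 1L) stop_input("`n_draws` must be >= 1")
  structure(list(n_draws = n_draws, seed = as.integer(seed)),
            class = "mc_spec")
}

#' Standard deviation of ln(RR) implied by a 95% confidence interval
#'
#' @param risk a [risk_model()].
#' @return numeric scalar, `(ln hi - ln lo) / (2 * 1.959964)`.
#' @examples
#' sd_log_rr(risk_model(1.19, c(1.09, 1.29)))  # ~0.04298
#' @export
sd_log_rr <- function(risk) {
  stopifnot(inherits(risk, "risk_model"))
  (log(risk$ci[2]) - log(risk$ci[1])) / (2 * stats::qnorm(0.975))
}

#' Sample relative-risk draws
#'
#' Draws are `exp(Normal(ln rr, sd))` with `sd` from [sd_log_rr()];
#' deterministic given the spec's seed. One draw applies to every cell and
#' day of a Monte Carlo replicate, because the RR is a single national
#' parameter.
#'
#' @param risk a [risk_model()].
#' @param spec an [mc_spec()].
#' @return numeric vector of `n_draws` RR values.
#' @export
sample_rr <- function(risk, spec) {
  stopifnot(inherits(risk, "risk_model"), inherits(spec, "mc_spec"))
  sd <- sd_log_rr(risk)
  set.seed(spec$seed)
  exp(stats::rnorm(spec$n_draws, mean = log(risk$rr), sd = sd))
}

#' Empirical percentile confidence interval
#'
#' The interval is the pair of `(1-level)/2` and `1-(1-level)/2` sample
#' percentiles (linear interpolation, type 7) of the flattened empirical
#' distribution. For observed-climate estimates the input is the vector of
#' coefficient-draw estimates; for scenario estimates it is the draws x
#' models matrix, flattened so the interval reflects both coefficient
#' imprecision and climate-model spread.
#'
#' @param estimates numeric vector or matrix of estimates.
#' @param level interval mass in `(0, 1)` (default 0.95).
#' @return named numeric `c(lo, hi)`.
#' @examples
#' empirical_ci(1:1000)  # 25.975, 975.025
#' @export
empirical_ci <- function(estimates, level = 0.95) {
  x <- as.vector(estimates)
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop_input("`estimates` must be non-empty")
  if (level <= 0 || level >= 1) stop_input("`level` must be in (0, 1)")
  q <- quantile7(x, c((1 - level) / 2, 1 - (1 - level) / 2))
  stats::setNames(q, c("lo", "hi"))
}

#' Rescale a burden result under alternative RR draws
#'
#' The attributable burden is linear in the attributable fraction:
#' `aPTB(RR) = exposedBase * (RR - 1)/RR`, where `exposedBase` is the
#' baseline PTB mass on exposed warm-season days already stored in the
#' burden result. Each draw therefore yields the full annual series
#' without re-running detection.
#'
#' @param result a `burden_result`.
#' @param rr_draws numeric vector of RR draws from [sample_rr()].
#' @return matrix draws x years of annual national attributable PTBs.
#' @export
burden_draws <- function(result, rr_draws) {
  stopifnot(inherits(result, "burden_result"))
  if (any(rr_draws <= 0)) stop_input("RR draws must be positive")
  af <- (rr_draws - 1) / rr_draws
  outer(af, result$exposed_base_annual)
}

#' Confidence intervals for annual and mean-annual attributable burden
#'
#' For a single (observed-climate) burden result the empirical distribution
#' is over coefficient draws only; for an ensemble (list of burden results,
#' one per climate model) it is flattened over draws x models, following
#' the scenario-uncertainty design.
#'
#' @param results a `burden_result` or list of them (one per model).
#' @param risk a [risk_model()].
#' @param spec an [mc_spec()].
#' @param level interval mass (default 0.95).
#' @return data.frame with one row per year plus a `mean_annual` row:
#'   `quantity`, `point`, `lo`, `hi`, `n_draws`, `n_models`.
#' @export
burden_ci <- function(results, risk, spec, level = 0.95) {
  if (inherits(results, "burden_result")) results <- list(results)
  stopifnot(length(results) >= 1L)
  draws <- sample_rr(risk, spec)
  per_model <- lapply(results, burden_draws, rr_draws = draws)
  yrs <- colnames(per_model[[1]])
  point_annual <- Reduce(`+`, lapply(results, function(b) b$annual)) /
    length(results)

  rows <- lapply(seq_along(yrs), function(j) {
    flat <- unlist(lapply(per_model, function(m) m[, j]))
    ci <- empirical_ci(flat, level)
    data.frame(quantity = yrs[j], point = unname(point_annual[j]),
               lo = ci[["lo"]], hi = ci[["hi"]])
  })
  # mean over years within each draw, flattened across models
  mean_flat <- unlist(lapply(per_model, rowMeans))
  ci <- empirical_ci(mean_flat, level)
  rows <- c(rows, list(data.frame(quantity = "mean_annual",
                                  point = mean(point_annual),
                                  lo = ci[["lo"]], hi = ci[["hi"]])))
  out <- do.call(rbind, rows)
  out$n_draws <- spec$n_draws
  out$n_models <- length(results)
  rownames(out) <- NULL
  out
}
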