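#' Simulation configuration for a synthetic CLS screen
#'
#' Bundles every knob of the synthetic competitive-aging screen. Defaults
#' emulate the design of a high-throughput nitrogen-restriction CLS screen:
#' strains aged in stationary phase for up to 21 days and sampled every other
#' day from day 3, outgrowths read every 150 min over 14 h, a 2:1
#' mutant:reference mixing ratio, and 264 wild-type-vs-wild-type replicate
#' co-cultures that supply the empirical null. Wild-type death rates default
#' to the fitted per-day rates of a wild type aged on glutamine
#' (non-restricted, \code{NR}) and GABA (dietary restriction, \code{DR}),
#' so that dietary restriction roughly doubles the wild-type half-life.
#'
#' @param seed integer seed; all generator randomness flows from it.
#' @param n_mutants number of mutant (RFP-labelled) strains.
#' @param n_wt_replicates number of independent WT-vs-WT co-cultures.
#' @param ages_days strictly increasing stationary-phase ages (days).
#' @param outgrowth_times_hr outgrowth sampling grid (hours).
#' @param mix_ratio initial viable mutant:reference ratio (2 means 2:1).
#' @param noise_cv coefficient of variation of the multiplicative
#'   (lognormal) fluorescence noise per reading.
#' @param outlier_rate fraction of fluorescence readings replaced by a
#'   grossly corrupted value (10x or 0.1x); must be below 0.2.
#' @param well_sd standard deviation (per day) of the per-co-culture random
#'   perturbation of the mutant death rate, emulating well-to-well
#'   experimental variability shared by mutants and WT replicates.
#' @param od_sd additive Gaussian noise on OD600 readings.
#' @param od_baseline optical-density offset of medium and plate.
#' @param carrying_capacity OD600 at which outgrowths saturate.
#' @param inoculum_od total viable OD-equivalent inoculated at age 0.
#' @param fl_scale_rfp,fl_scale_cfp fluorescence units per OD unit of the
#'   mutant (RFP) and reference (CFP) populations.
#' @param death_rate_wt named per-day wild-type death rates, one per
#'   condition (default \code{c(NR = 0.057, DR = 0.029)}).
#' @param doubling_time_wt_hr wild-type exponential doubling time (hours).
#'
#' @return An object of class \code{"sim_config"} (a validated list).
#' @seealso [simulate_panel()], [simulate_screen()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_mutants = 10, n_wt_replicates = 5)
#' cfg$ages_days
sim_config <- function(seed = 1L,
                       n_mutants = 200L,
                       n_wt_replicates = 264L,
                       ages_days = seq(3, 21, by = 2),
                       outgrowth_times_hr = seq(0, 14, by = 2.5),
                       mix_ratio = 2,
                       noise_cv = 0.05,
                       outlier_rate = 0.01,
                       well_sd = 0.003,
                       od_sd = 0.005,
                       od_baseline = 0.04,
                       carrying_capacity = 1.2,
                       inoculum_od = 0.04,
                       fl_scale_rfp = 2000,
                       fl_scale_cfp = 2200,
                       death_rate_wt = c(NR = 0.057, DR = 0.029),
                       doubling_time_wt_hr = 2.7) {
  stopifnot(length(seed) == 1, is.finite(seed))
  if (!is.numeric(n_mutants) || length(n_mutants) != 1 || n_mutants < 0 ||
      n_mutants != round(n_mutants)) {
    stop("`n_mutants` must be a single non-negative integer", call. = FALSE)
  }
  if (!is.numeric(n_wt_replicates) || n_wt_replicates < 2 ||
      n_wt_replicates != round(n_wt_replicates)) {
    stop("`n_wt_replicates` must be an integer >= 2", call. = FALSE)
  }
  if (length(ages_days) < 3 || any(diff(ages_days) <= 0)) {
    stop("`ages_days` must be strictly increasing with >= 3 ages",
         call. = FALSE)
  }
  if (length(outgrowth_times_hr) < 2 || any(diff(outgrowth_times_hr) <= 0)) {
    stop("`outgrowth_times_hr` must be strictly increasing", call. = FALSE)
  }
  if (mix_ratio <= 0) stop("`mix_ratio` must be > 0", call. = FALSE)
  if (outlier_rate < 0 || outlier_rate >= 0.2) {
    stop("`outlier_rate` must be in [0, 0.2)", call. = FALSE)
  }
  if (noise_cv < 0 || well_sd < 0 || od_sd < 0) {
    stop("noise parameters must be non-negative", call. = FALSE)
  }
  if (is.null(names(death_rate_wt)) || any(names(death_rate_wt) == "")) {
    stop("`death_rate_wt` must be a named vector, one rate per condition",
         call. = FALSE)
  }
  if (any(death_rate_wt < 0) || any(!is.finite(death_rate_wt))) {
    stop("wild-type death rates must be finite and non-negative",
         call. = FALSE)
  }
  if (doubling_time_wt_hr <= 1.5 || doubling_time_wt_hr >= 6) {
    stop("`doubling_time_wt_hr` must lie in (1.5, 6) hours", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed),
    n_mutants = as.integer(n_mutants),
    n_wt_replicates = as.integer(n_wt_replicates),
    ages_days = as.numeric(ages_days),
    outgrowth_times_hr = as.numeric(outgrowth_times_hr),
    mix_ratio = mix_ratio,
    noise_cv = noise_cv,
    outlier_rate = outlier_rate,
    well_sd = well_sd,
    od_sd = od_sd,
    od_baseline = od_baseline,
    carrying_capacity = carrying_capacity,
    inoculum_od = inoculum_od,
    fl_scale_rfp = fl_scale_rfp,
    fl_scale_cfp = fl_scale_cfp,
    death_rate_wt = death_rate_wt,
    doubling_time_wt_hr = doubling_time_wt_hr
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic CLS screen configuration\n")
  cat("  strains   :", x$n_mutants, "mutants +", x$n_wt_replicates,
      "WT replicate co-cultures\n")
  cat("  conditions:", paste(names(x$death_rate_wt), collapse = ", "),
      " (WT death rates", paste(format(x$death_rate_wt), collapse = ", "),
      "per day)\n")
  cat("  ages      :", paste(x$ages_days, collapse = ", "), "days\n")
  cat("  outgrowth :", length(x$outgrowth_times_hr), "readings over",
      max(x$outgrowth_times_hr), "h; mix", x$mix_ratio, ": 1\n")
  cat("  noise     : fluorescence CV", x$noise_cv, "; outlier rate",
      x$outlier_rate, "; well sd", x$well_sd, "/day\n")
  invisible(x)
}
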