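#' Extract doubling time and threshold-crossing time from an outgrowth
#'
#' The doubling time comes from a log-linear regression of OD600 on time
#' over the exponential window (OD within \code{window}, default 0.05--0.5);
#' the time shift \code{t_cross_hr} to reach the mid-exponential threshold
#' (default OD600 = 0.3) is found by log-linear interpolation between the
#' bracketing readings. Curves that never reach the threshold are flagged
#' censored.
#'
#' @param curve an [outgrowth_curve()] (needs \code{time_hr}, \code{od600}).
#' @param od_threshold mid-exponential OD600 threshold.
#' @param window OD600 range defining the exponential fit window.
#' @return List of class \code{"outgrowth_params"}: \code{doubling_time_hr},
#'   \code{t_cross_hr}, \code{censored}, \code{fit_window} (times used),
#'   \code{growth_rate_hr}.
#' @export
#' @examples
#' tt <- seq(0, 12, 0.5)
#' cu <- outgrowth_curve(tt, od600 = 0.05 * 2^(tt / 2))
#' extract_outgrowth_params(cu)$doubling_time_hr   # 2
extract_outgrowth_params <- function(curve, od_threshold = 0.3,
                                     window = c(0.05, 0.5)) {
  tt <- curve$time_hr
  od <- curve$od600
  stopifnot(length(tt) >= 2, od_threshold > 0)
  in_win <- od >= window[1] & od <= window[2] & od > 0
  if (sum(in_win) < 2) {
    # fall back to the two largest positive readings below saturation
    pos <- which(od > 0)
    if (length(pos) < 2) stop("not enough positive OD readings", call. = FALSE)
    in_win <- seq_along(od) %in% utils::tail(pos, 3)
  }
  fit <- lm(log(od[in_win]) ~ tt[in_win])
  g <- unname(coef(fit)[2])
  if (!is.finite(g) || g <= 0) {
    return(structure(list(doubling_time_hr = NA_real_, t_cross_hr = NA_real_,
                          censored = TRUE, fit_window = tt[in_win],
                          growth_rate_hr = g),
                     class = "outgrowth_params"))
  }
  dt <- log(2) / g

  if (max(od) < od_threshold) {
    return(structure(list(doubling_time_hr = dt, t_cross_hr = NA_real_,
                          censored = TRUE, fit_window = tt[in_win],
                          growth_rate_hr = g),
                     class = "outgrowth_params"))
  }
  if (od[1] >= od_threshold) {
    tc <- tt[1]
  } else {
    i <- which(od >= od_threshold)[1]
    t0 <- tt[i - 1]; t1 <- tt[i]
    y0 <- log(max(od[i - 1], 1e-12)); y1 <- log(od[i])
    tc <- t0 + (log(od_threshold) - y0) / (y1 - y0) * (t1 - t0)
  }
  structure(list(doubling_time_hr = dt, t_cross_hr = tc, censored = FALSE,
                 fit_window = tt[in_win], growth_rate_hr = g),
            class = "outgrowth_params")
}

#' @export
print.outgrowth_params <- function(x, digits = 4, ...) {
  cat("Outgrowth kinetics: doubling time",
      format(x$doubling_time_hr, digits = digits), "h; threshold crossing",
      if (x$censored) "censored" else
        paste(format(x$t_cross_hr, digits = digits), "h"), "\n")
  invisible(x)
}

#' Viability from an outgrowth time shift
#'
#' A culture whose viable inoculum halves needs one extra doubling time to
#' reach the same OD threshold, so the time shift between the aged and the
#' reference outgrowth converts to relative viability as
#' \eqn{100 \cdot 2^{-\Delta t / t_{double}}}.
#'
#' @param delta_t_hr time shift relative to the age-0 outgrowth (hours).
#' @param doubling_time_hr reference doubling time (hours, > 0).
#' @return Viability percent.
#' @export
#' @examples
#' viability_from_shift(0, 2)    # 100
#' viability_from_shift(2, 2)    # 50
viability_from_shift <- function(delta_t_hr, doubling_time_hr) {
  stopifnot(all(doubling_time_hr > 0))
  100 * 2^(-delta_t_hr / doubling_time_hr)
}

#' Build a viability curve from per-age outgrowth curves
#'
#' Takes the outgrowth curves of one strain and condition across
#' stationary-phase ages, extracts the threshold-crossing time of each, and
#' converts the time shift relative to the youngest age (taken as 100\%
#' viable by definition) into viability percentages using the reference
#' doubling time. Censored ages (outgrowth never reaches the threshold)
#' receive the viability floor.
#'
#' @param curves list of [outgrowth_curve()]s across ages (one strain and
#'   condition), or a \code{"plate_data"} subset.
#' @param od_threshold mid-exponential OD600 threshold.
#' @param reference_dt \code{"t0"} uses the age-0 curve's doubling time for
#'   all ages (default); \code{"own"} uses each age's own.
#' @param floor_percent viability assigned to censored ages.
#' @param window exponential-window OD range (see
#'   [extract_outgrowth_params()]).
#' @return Data frame of class \code{"viability_curve"}: \code{age_days},
#'   \code{viability_percent}, \code{censored}; attributes \code{strain_id},
#'   \code{condition}, \code{doubling_time_hr}.
#' @export
viability_curve <- function(curves, od_threshold = 0.3,
                            reference_dt = c("t0", "own"),
                            floor_percent = 0.1, window = c(0.05, 0.5)) {
  reference_dt <- match.arg(reference_dt)
  if (is.data.frame(curves)) curves <- split_curves(curves)
  ages <- vapply(curves, function(cu) as.numeric(attr(cu, "age_days")),
                 numeric(1))
  o <- order(ages)
  curves <- curves[o]
  ages <- ages[o]
  pars <- lapply(curves, extract_outgrowth_params,
                 od_threshold = od_threshold, window = window)
  p0 <- pars[[1]]
  if (p0$censored) {
    stop("reference (youngest-age) outgrowth never reaches the threshold",
         call. = FALSE)
  }
  via <- numeric(length(ages))
  cens <- logical(length(ages))
  for (i in seq_along(ages)) {
    pi <- pars[[i]]
    if (pi$censored || is.na(pi$t_cross_hr)) {
      via[i] <- floor_percent
      cens[i] <- TRUE
      next
    }
    dt_ref <- if (reference_dt == "t0") p0$doubling_time_hr
              else pi$doubling_time_hr
    via[i] <- viability_from_shift(pi$t_cross_hr - p0$t_cross_hr, dt_ref)
  }
  structure(
    data.frame(age_days = ages, viability_percent = via, censored = cens),
    strain_id = attr(curves[[1]], "strain_id"),
    condition = attr(curves[[1]], "condition"),
    doubling_time_hr = p0$doubling_time_hr,
    class = c("viability_curve", "data.frame")
  )
}

#' Simulate a noisy viability curve with known death rate
#'
#' Generates stationary-phase viability percentages decaying exponentially
#' from \code{n0} at rate \code{r} per day, with additive Gaussian noise in
#' percentage points (truncated at a small positive floor). Ground truth
#' for testing the decay-fitting machinery.
#'
#' @param ages_days sampling ages.
#' @param r per-day death rate.
#' @param n0 viability percent at age 0.
#' @param noise_sd additive noise, percentage points.
#' @param seed optional seed.
#' @return A \code{"viability_curve"} data frame.
#' @export
simulate_viability_curve <- function(ages_days = seq(0, 24, by = 3), r,
                                     n0 = 100, noise_sd = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- n0 * exp(-r * ages_days)
  if (noise_sd > 0) v <- pmax(v + rnorm(length(v), 0, noise_sd), 0.01)
  structure(
    data.frame(age_days = ages_days, viability_percent = v,
               censored = FALSE),
    class = c("viability_curve", "data.frame")
  )
}

#' Fit an exponential decay model to a viability curve
#'
#' Nonlinear least squares of \eqn{N(T) = N_0 e^{-rT}} on all data points,
#' initialised from the log-linear fit. The half-life is the age at which
#' the fitted curve crosses 50\% viability, \eqn{\ln(N_0/50)/r}, which
#' equals \eqn{\ln 2 / r} when \eqn{N_0 = 100}; it is \code{NA} when the
#' fitted \eqn{N_0} is at or below 50. An increasing viability trend floors
#' the death rate at 1e-6 with a warning.
#'
#' @param curve a \code{"viability_curve"} (or data frame with
#'   \code{age_days} and \code{viability_percent}); needs >= 4 points
#'   spanning >= 6 days.
#' @return Object of class \code{"decay_fit"}: \code{n0}, \code{r},
#'   \code{half_life_days}, \code{rss}, \code{fitted}, \code{residuals},
#'   \code{data}. Supports \code{print}, \code{coef}, \code{predict},
#'   \code{residuals} and \code{plot}.
#' @export
#' @examples
#' vc <- simulate_viability_curve(r = log(2) / 10, noise_sd = 0)
#' fit_decay(vc)$half_life_days   # 10
fit_decay <- function(curve) {
  age <- as.numeric(curve$age_days)
  v <- as.numeric(curve$viability_percent)
  keep <- is.finite(age) & is.finite(v) & v > 0
  age <- age[keep]; v <- v[keep]
  if (length(age) < 4) stop("need >= 4 viability points", call. = FALSE)
  if (diff(range(age)) < 6) {
    stop("viability points must span >= 6 days", call. = FALSE)
  }
  ll <- lm(log(v) ~ age)
  r0 <- -unname(coef(ll)[2])
  n00 <- exp(unname(coef(ll)[1]))
  if (r0 <= 0) {
    warning("increasing viability trend; death rate floored at 1e-6",
            call. = FALSE)
    r0 <- 1e-6
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ n0 * exp(-r * age),
                      start = list(n0 = n00, r = r0),
                      lower = c(n0 = 1e-6, r = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("decay fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- coef(fit)
  n0 <- unname(cf["n0"])
  r <- unname(cf["r"])
  fitted_v <- n0 * exp(-r * age)
  hl <- if (n0 > 50) log(n0 / 50) / r else NA_real_
  structure(list(
    n0 = n0, r = r, half_life_days = hl,
    rss = sum((v - fitted_v)^2),
    coefficients = c(n0 = n0, r = r),
    fitted = fitted_v, residuals = v - fitted_v,
    data = data.frame(age_days = age, viability_percent = v),
    strain_id = attr(curve, "strain_id"),
    condition = attr(curve, "condition")
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, digits = 4, ...) {
  cat("Exponential viability decay fit\n")
  cat("  N0        =", format(x$n0, digits = digits), "%\n")
  cat("  r         =", format(x$r, digits = digits), "per day\n")
  cat("  half-life =", format(x$half_life_days, digits = digits), "days\n")
  cat("  RSS       =", format(x$rss, digits = digits), " (n =",
      nrow(x$data), ")\n")
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) object$coefficients

#' @export
residuals.decay_fit <- function(object, ...) object$residuals

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  age <- if (is.null(newdata)) object$data$age_days else newdata$age_days
  object$n0 * exp(-object$r * age)
}

#' @export
plot.decay_fit <- function(x, ...) {
  plot(x$data$age_days, x$data$viability_percent, log = "y",
       xlab = "Stationary-phase age (days)", ylab = "Viability (%)",
       pch = 19, ...)
  ag <- seq(min(x$data$age_days), max(x$data$age_days), length.out = 100)
  graphics::lines(ag, x$n0 * exp(-x$r * ag))
  graphics::abline(h = 50, lty = 3)
  invisible(x)
}

#' Percent lifespan extension between two half-lives
#'
#' \eqn{100 (h_{DR} - h_{NR}) / h_{NR}}; e.g. half-lives of 14.7 and 28.1
#' days give a 91\% extension. The exact value is returned; round for
#' reporting.
#'
#' @param half_life_nr,half_life_dr half-lives in days (> 0).
#' @return Percent extension (can be negative).
#' @export
#' @examples
#' round(percent_extension(14.7, 28.1))   # 91
percent_extension <- function(half_life_nr, half_life_dr) {
  stopifnot(all(half_life_nr > 0), all(half_life_dr > 0))
  100 * (half_life_dr - half_life_nr) / half_life_nr
}

#' Compare death rates between two replicate groups
#'
#' Two-sample t-test (Welch by default) on per-replicate death rates; the
#' standard significance test for small-scale CLS comparisons.
#'
#' @param rates_a,rates_b numeric death-rate vectors, >= 3 each.
#' @param var.equal use the pooled-variance test instead of Welch.
#' @return The \code{htest} object from [stats::t.test()].
#' @export
compare_death_rates <- function(rates_a, rates_b, var.equal = FALSE) {
  if (length(rates_a) < 3 || length(rates_b) < 3) {
    stop("need >= 3 replicates per group", call. = FALSE)
  }
  t.test(rates_a, rates_b, var.equal = var.equal)
}
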