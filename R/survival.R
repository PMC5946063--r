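#' Interpolate an outgrowth curve at a fixed time
#'
#' Channel-wise linear interpolation on log-transformed signals between the
#' two bracketing readings (growth is exponential around mid-outgrowth, so
#' log-space interpolation is the natural choice); exact at grid points.
#' Signals are floored before the log so zero readings cannot produce
#' \code{-Inf}.
#'
#' @param curve an [outgrowth_curve()] (or data frame with \code{time_hr},
#'   \code{od600}, \code{rfp}, \code{cfp}).
#' @param t_hr interpolation time; must lie within the sampled range.
#' @param floor signal floor applied before log-transforming fluorescence.
#' @return Named numeric vector \code{c(od600, rfp, cfp)}.
#' @export
#' @examples
#' cu <- outgrowth_curve(c(9, 11), od600 = c(0.1, 0.4),
#'                       rfp = c(100, 400), cfp = c(200, 800))
#' interpolate_at(cu, 10)   # geometric means: rfp 200, cfp 400
interpolate_at <- function(curve, t_hr, floor = 1e-12) {
  tt <- curve$time_hr
  if (length(t_hr) != 1 || t_hr < min(tt) || t_hr > max(tt)) {
    stop("interpolation time ", t_hr, " outside sampled range [",
         min(tt), ", ", max(tt), "]", call. = FALSE)
  }
  interp1 <- function(y) {
    exp(approx(tt, log(pmax(y, floor)), xout = t_hr, ties = "ordered")$y)
  }
  c(od600 = interp1(curve$od600), rfp = interp1(curve$rfp),
    cfp = interp1(curve$cfp))
}

#' Log-ratio series of a strain's competitive outgrowths
#'
#' For one strain and condition, interpolates the RFP and CFP channels of
#' each age's outgrowth at a fixed time (default 10 h) and returns the
#' natural log of their ratio as a function of stationary-phase age. Ages
#' where either channel is at or below the signal floor are dropped with a
#' warning; fewer than three usable ages is an error.
#'
#' @param curves list of [outgrowth_curve()]s for one strain and condition
#'   (e.g. from [split_curves()]).
#' @param t_hr fixed interpolation time in the outgrowth (hours).
#' @param floor signal floor; readings at or below it are unusable.
#' @return Data frame with columns \code{age_days} and \code{log_ratio},
#'   ordered by age.
#' @export
log_ratio_series <- function(curves, t_hr = 10, floor = 1) {
  if (inherits(curves, "outgrowth_curve")) curves <- list(curves)
  ages <- vapply(curves, function(cu) as.numeric(attr(cu, "age_days")),
                 numeric(1))
  o <- order(ages)
  curves <- curves[o]
  ages <- ages[o]
  lr <- rep(NA_real_, length(curves))
  for (i in seq_along(curves)) {
    sig <- interpolate_at(curves[[i]], t_hr, floor = 0)
    if (is.na(sig["rfp"]) || is.na(sig["cfp"]) ||
        sig["rfp"] <= floor || sig["cfp"] <= floor) {
      warning("dropping age ", ages[i], ": channel at or below signal floor",
              call. = FALSE)
      next
    }
    lr[i] <- log(sig[["rfp"]] / sig[["cfp"]])
  }
  keep <- !is.na(lr)
  if (sum(keep) < 3) {
    stop("fewer than 3 usable ages for log-ratio series", call. = FALSE)
  }
  data.frame(age_days = ages[keep], log_ratio = lr[keep])
}

# Tight IRLS bisquare slope fit; x, y plain numeric vectors.
# Initialised from the Theil-Sen line rather than OLS: the bisquare psi is
# redescending, and an OLS start can be captured by a local minimum when
# several gross outliers sit at one end of the age range. Theil-Sen has a
# 29% breakdown point, so the IRLS starts near the majority line. On
# exactly collinear data the result equals ordinary least squares.
# Returns list(intercept, slope, se, sigma, weights, fitted, iter, converged).
irls_bisquare <- function(x, y, tune = 4.685, max_iter = 50, tol = 1e-10) {
  n <- length(x)
  wls <- function(w) {
    sw <- sum(w)
    xb <- sum(w * x) / sw
    yb <- sum(w * y) / sw
    sxx <- sum(w * (x - xb)^2)
    b <- sum(w * (x - xb) * (y - yb)) / sxx
    a <- yb - b * xb
    list(a = a, b = b, sxx = sxx)
  }
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  ts_b <- median(((y[ij[2, ]] - y[ij[1, ]]) / dx)[dx != 0])
  fit <- list(a = median(y - ts_b * x), b = ts_b, sxx = NA_real_)
  w <- rep(1, n)
  slope <- fit$b
  sigma <- NA_real_
  conv <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    r <- y - (fit$a + fit$b * x)
    # floor the MAD scale so an (almost) exact majority fit still rejects
    # gross outliers instead of collapsing the scale to zero; on exactly
    # collinear data all residuals vanish and the fit reduces to OLS
    sigma <- max(median(abs(r)) / 0.6745, 1e-8 * max(abs(r)),
                 .Machine$double.eps)
    u <- r / (tune * sigma)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < 2 || sum(w * (x - mean(x))^2) <= 0) {
      fit <- wls(rep(1, n))
      break
    }
    fit <- wls(w)
    if (abs(fit$b - slope) < tol * max(1, abs(slope))) {
      slope <- fit$b
      conv <- TRUE
      break
    }
    slope <- fit$b
  }
  if (is.na(fit$sxx)) fit <- wls(w)
  r <- y - (fit$a + fit$b * x)
  dof <- max(n - 2, 1)
  s2 <- sum(w * r^2) / dof
  se <- sqrt(s2 / fit$sxx)
  list(intercept = fit$a, slope = fit$b, se = se,
       sigma = if (is.finite(sigma)) sigma else 0,
       weights = w, residuals = r, fitted = fit$a + fit$b * x,
       iter = it, converged = conv)
}

#' Fit a survival coefficient by robust regression
#'
#' The survival coefficient \eqn{s} is the slope (log-units per day) of a
#' robust linear regression of the outgrowth log-ratio
#' \eqn{\ln(\mathrm{RFP}/\mathrm{CFP})} on stationary-phase age. The fit is
#' iteratively reweighted least squares with Tukey bisquare weights
#' (tuning constant 4.685) and scale re-estimated each iteration from the
#' median absolute residual; on exactly collinear data it reduces to
#' ordinary least squares. Negative \eqn{s}: the strain dies faster than
#' the reference; positive: slower.
#'
#' @param series data frame with \code{age_days} and \code{log_ratio}
#'   (from [log_ratio_series()]), or a list of curves which is passed
#'   through [log_ratio_series()] first.
#' @param tune bisquare tuning constant.
#' @param strain_id,condition identity carried into the result.
#' @param ... passed to [log_ratio_series()] when `series` is a curve list.
#' @return An object of class \code{"cls_fit"} with components
#'   \code{s}, \code{se_s}, \code{intercept}, \code{n_ages},
#'   \code{residual_scale}, \code{coefficients}, \code{weights},
#'   \code{residuals}, \code{fitted}, \code{data}, \code{converged}.
#'   Supports \code{print}, \code{summary}, \code{coef}, \code{predict} and
#'   \code{residuals}.
#' @export
#' @examples
#' ser <- data.frame(age_days = c(3, 5, 7, 9),
#'                   log_ratio = c(0, -0.2, -0.4, -0.6))
#' fit <- fit_survival(ser)
#' coef(fit)     # slope -0.1 / day
fit_survival <- function(series, tune = 4.685,
                         strain_id = NA_character_,
                         condition = NA_character_, ...) {
  if (is.list(series) && !is.data.frame(series)) {
    if (length(series) > 0 && inherits(series[[1]], "outgrowth_curve")) {
      if (is.na(strain_id)) strain_id <- attr(series[[1]], "strain_id")
      if (is.na(condition)) condition <- attr(series[[1]], "condition")
    }
    series <- log_ratio_series(series, ...)
  }
  x <- as.numeric(series$age_days)
  y <- as.numeric(series$log_ratio)
  if (length(x) < 3) stop("need >= 3 ages to fit s", call. = FALSE)
  if (sd(x) == 0) stop("degenerate series: all ages equal", call. = FALSE)
  f <- irls_bisquare(x, y, tune = tune)
  structure(list(
    strain_id = strain_id, condition = condition,
    s = f$slope, se_s = f$se, intercept = f$intercept,
    n_ages = length(x), residual_scale = f$sigma,
    coefficients = c(intercept = f$intercept, s = f$slope),
    weights = f$weights, residuals = f$residuals, fitted = f$fitted,
    data = data.frame(age_days = x, log_ratio = y),
    converged = f$converged, qc_pass = TRUE
  ), class = "cls_fit")
}

#' @export
print.cls_fit <- function(x, digits = 4, ...) {
  id <- if (!is.na(x$strain_id)) paste0(" [", x$strain_id,
                                        if (!is.na(x$condition))
                                          paste0(", ", x$condition), "]")
        else ""
  cat("Robust survival-coefficient fit", id, "\n", sep = "")
  cat("  s = ", format(x$s, digits = digits),
      " +/- ", format(x$se_s, digits = digits),
      " per day  (", x$n_ages, " ages)\n", sep = "")
  invisible(x)
}

#' @export
coef.cls_fit <- function(object, ...) object$coefficients

#' @export
residuals.cls_fit <- function(object, ...) object$residuals

#' @export
predict.cls_fit <- function(object, newdata = NULL, ...) {
  age <- if (is.null(newdata)) object$data$age_days else newdata$age_days
  object$intercept + object$s * age
}

#' @export
summary.cls_fit <- function(object, ...) {
  z <- object$s / object$se_s
  structure(list(fit = object, z = z,
                 p = 2 * pnorm(-abs(z)),
                 down_weighted = sum(object$weights < 0.5)),
            class = "summary.cls_fit")
}

#' @export
print.summary.cls_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("  intercept        :", format(x$fit$intercept, digits = digits), "\n")
  cat("  residual scale   :", format(x$fit$residual_scale, digits = digits),
      "\n")
  cat("  slope z, p       :", format(x$z, digits = digits), ",",
      format(x$p, digits = digits), "\n")
  cat("  points w < 0.5   :", x$down_weighted, "\n")
  invisible(x)
}

#' Score a whole screen: survival coefficient per strain and condition
#'
#' Computes the log-ratio series at a fixed interpolation time for every
#' (strain, condition) in a plate table and fits the robust survival
#' coefficient. Strains with fewer than three usable ages are reported with
#' \code{NA} coefficients and \code{qc_pass = FALSE}.
#'
#' @param plates plate data (long format, e.g. [read_plate_tsv()] or
#'   \code{simulate_screen()$plates}).
#' @param t_hr fixed interpolation time (hours).
#' @param floor fluorescence signal floor.
#' @param tune bisquare tuning constant.
#' @return Data frame of class \code{"cls_scores"}: \code{strain_id},
#'   \code{condition}, \code{s}, \code{se_s}, \code{n_ages},
#'   \code{intercept}, \code{residual_scale}, \code{qc_pass}.
#' @export
score_screen <- function(plates, t_hr = 10, floor = 1, tune = 4.685) {
  stopifnot(all(c("strain_id", "condition", "age_days", "time_hr",
                  "rfp", "cfp") %in% names(plates)))
  # fast path: the interpolation time is on the sampling grid for a curve
  # whenever a reading exists at exactly t_hr; otherwise log-interpolate.
  key <- paste(plates$strain_id, plates$condition, sep = "\r")
  akey <- paste(key, plates$age_days, sep = "\r")
  at_t <- plates$time_hr == t_hr
  have_exact <- akey %in% akey[at_t]

  lr_tab <- if (all(have_exact)) {
    sub <- plates[at_t, , drop = FALSE]
    data.frame(key = paste(sub$strain_id, sub$condition, sep = "\r"),
               strain_id = sub$strain_id, condition = sub$condition,
               age_days = sub$age_days, rfp = sub$rfp, cfp = sub$cfp,
               stringsAsFactors = FALSE)
  } else {
    rows <- split(seq_len(nrow(plates)), akey)
    do.call(rbind, lapply(rows, function(i) {
      sub <- plates[i, , drop = FALSE]
      sub <- sub[order(sub$time_hr), , drop = FALSE]
      sig <- tryCatch(interpolate_at(sub, t_hr, floor = 0),
                      error = function(e) c(od600 = NA, rfp = NA, cfp = NA))
      data.frame(key = paste(sub$strain_id[1], sub$condition[1], sep = "\r"),
                 strain_id = sub$strain_id[1], condition = sub$condition[1],
                 age_days = sub$age_days[1],
                 rfp = sig[["rfp"]], cfp = sig[["cfp"]],
                 stringsAsFactors = FALSE)
    }))
  }
  usable <- !is.na(lr_tab$rfp) & !is.na(lr_tab$cfp) &
    lr_tab$rfp > floor & lr_tab$cfp > floor
  lr_tab$log_ratio <- ifelse(usable, log(lr_tab$rfp / lr_tab$cfp), NA_real_)

  groups <- split(seq_len(nrow(lr_tab)), lr_tab$key)
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    i <- groups[[gi]]
    sub <- lr_tab[i, , drop = FALSE]
    ok <- !is.na(sub$log_ratio)
    if (sum(ok) >= 3 && sd(sub$age_days[ok]) > 0) {
      f <- irls_bisquare(sub$age_days[ok], sub$log_ratio[ok], tune = tune)
      out[[gi]] <- data.frame(
        strain_id = sub$strain_id[1], condition = sub$condition[1],
        s = f$slope, se_s = f$se, n_ages = sum(ok),
        intercept = f$intercept, residual_scale = f$sigma, qc_pass = TRUE,
        stringsAsFactors = FALSE)
    } else {
      out[[gi]] <- data.frame(
        strain_id = sub$strain_id[1], condition = sub$condition[1],
        s = NA_real_, se_s = NA_real_, n_ages = sum(ok),
        intercept = NA_real_, residual_scale = NA_real_, qc_pass = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$condition, res$strain_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("cls_scores", "data.frame")
  res
}

#' Quality-control filter for screen scores
#'
#' Flags strains with slow growth or low fluorescence signal, mirroring the
#' discard rules of plate-based competition screens: a strain fails QC in a
#' condition if (i) fewer than \code{min_ages} usable ages entered the fit,
#' (ii) its peak fluorescence never exceeds \code{signal_mult} times the
#' floor, or (iii) its saturation OD is below \code{od_frac} times the
#' plate-median saturation OD. Thresholds are recorded as attributes.
#'
#' @param scores a \code{"cls_scores"} table from [score_screen()].
#' @param plates the raw plate data the scores came from.
#' @param floor fluorescence signal floor.
#' @param signal_mult peak-fluorescence multiple of the floor required.
#' @param od_frac fraction of plate-median saturation OD required.
#' @param min_ages minimum usable ages.
#' @return `scores` with `qc_pass` updated; attribute \code{"qc_thresholds"}.
#' @export
qc_filter <- function(scores, plates, floor = 1, signal_mult = 5,
                      od_frac = 0.5, min_ages = 3) {
  key_p <- paste(plates$strain_id, plates$condition, sep = "\r")
  peak_fl <- tapply(pmax(plates$rfp, plates$cfp), key_p, max)
  sat_od <- tapply(plates$od600, key_p, max)
  med_od <- tapply(plates$od600, plates$condition, function(v) median(v))
  # plate-median saturation OD per condition
  sat_by_cond <- tapply(plates$od600, key_p, max)
  cond_of <- sub("^.*\r", "", names(sat_by_cond))
  med_sat <- tapply(sat_by_cond, cond_of, median)

  key_s <- paste(scores$strain_id, scores$condition, sep = "\r")
  pf <- as.numeric(peak_fl[key_s])
  so <- as.numeric(sat_od[key_s])
  ms <- as.numeric(med_sat[scores$condition])
  fail <- (scores$n_ages < min_ages) |
    (!is.na(pf) & pf < signal_mult * floor) |
    (!is.na(so) & !is.na(ms) & so < od_frac * ms) |
    is.na(scores$s)
  scores$qc_pass <- !fail
  attr(scores, "qc_thresholds") <- list(
    floor = floor, signal_mult = signal_mult, od_frac = od_frac,
    min_ages = min_ages, plate_median_saturation_od = med_sat,
    median_od = med_od)
  scores
}
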