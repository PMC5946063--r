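test_that("interpolation is exact at grid points and geometric between them", {
  cu <- outgrowth_curve(c(9, 10, 11), od600 = c(0.1, 0.2, 0.4),
                        rfp = c(50, 60, 70), cfp = c(10, 20, 30))
  expect_equal(unname(interpolate_at(cu, 10)), c(0.2, 60, 20))

  cu2 <- outgrowth_curve(c(9, 11), od600 = c(0.1, 0.4),
                         rfp = c(100, 400), cfp = c(200, 800))
  sig <- interpolate_at(cu2, 10)
  expect_equal(unname(sig[["rfp"]]), 200)   # geometric mean in log space
  expect_equal(unname(sig[["cfp"]]), 400)

  expect_error(interpolate_at(cu2, 15), "outside sampled range")
})

test_that("log-ratio series is zero for equal channels and drops floored ages", {
  mk <- function(age, rfp, cfp) {
    outgrowth_curve(c(5, 10, 14), od600 = c(0.1, 0.5, 1),
                    rfp = rep(rfp, 3), cfp = rep(cfp, 3),
                    strain_id = "S", condition = "NR", age_days = age)
  }
  curves <- lapply(c(3, 5, 7, 9), mk, rfp = 100, cfp = 100)
  ser <- log_ratio_series(curves)
  expect_equal(ser$log_ratio, rep(0, 4))

  curves[[2]] <- mk(5, rfp = 100, cfp = 0)
  expect_warning(ser2 <- log_ratio_series(curves), "floor")
  expect_equal(nrow(ser2), 3)
  expect_false(5 %in% ser2$age_days)

  curves3 <- lapply(c(3, 5), mk, rfp = 100, cfp = 100)
  expect_error(log_ratio_series(curves3), "fewer than 3")
})

test_that("the robust fit equals OLS on exactly collinear data", {
  ser <- data.frame(age_days = c(3, 5, 7, 9),
                    log_ratio = c(0, -0.2, -0.4, -0.6))
  fit <- fit_survival(ser)
  expect_equal(fit$s, -0.100, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.3, tolerance = 1e-12)
  expect_equal(fit$n_ages, 4)

  const <- data.frame(age_days = c(3, 5, 7), log_ratio = c(0.4, 0.4, 0.4))
  fc <- fit_survival(const)
  expect_equal(fc$s, 0)
  expect_equal(fc$intercept, 0.4)

  expect_error(fit_survival(data.frame(age_days = c(5, 5, 5),
                                       log_ratio = c(1, 2, 3))),
               "degenerate")
  expect_error(fit_survival(data.frame(age_days = c(3, 5),
                                       log_ratio = c(0, 1))), ">= 3")
})

test_that("a single gross outlier barely moves the slope", {
  ages <- seq(3, 21, by = 2)
  clean <- data.frame(age_days = ages, log_ratio = 0.5 - 0.05 * ages)
  dirty <- clean
  dirty$log_ratio[4] <- dirty$log_ratio[4] + log(10)
  fit <- fit_survival(dirty)
  expect_lt(abs(fit$s - (-0.05)), 0.005)
})

test_that("the fit agrees with an independent robust regression on noisy data", {
  skip_if_not_installed("MASS")
  set.seed(33)
  for (i in 1:20) {
    ages <- seq(3, 21, by = 2)
    y <- 0.2 - 0.04 * ages + rnorm(length(ages), 0, 0.05)
    if (i %% 3 == 0) y[sample(length(y), 1)] <- y[1] + 2   # plant an outlier
    fit <- fit_survival(data.frame(age_days = ages, log_ratio = y))
    rl <- MASS::rlm(y ~ ages, psi = MASS::psi.bisquare, maxit = 100)
    expect_equal(fit$s, unname(coef(rl)[2]), tolerance = 0.01)
  }
})

test_that("cls_fit methods are coherent", {
  ser <- data.frame(age_days = c(3, 5, 7, 9, 11),
                    log_ratio = c(0.02, -0.09, -0.21, -0.28, -0.41))
  fit <- fit_survival(ser, strain_id = "mut1", condition = "NR")
  expect_s3_class(fit, "cls_fit")
  expect_named(coef(fit), c("intercept", "s"))
  expect_equal(predict(fit), fit$fitted)
  expect_equal(residuals(fit) + fit$fitted, ser$log_ratio)
  expect_output(print(fit), "mut1")
  expect_output(print(summary(fit)), "residual scale")
  expect_gt(fit$se_s, 0)
})

test_that("noiseless screens are recovered exactly (estimator consistency)", {
  cfg <- noiseless_config(seed = 4, n_mutants = 25, n_wt_replicates = 3)
  sim <- simulate_screen(cfg)
  sc <- score_screen(sim$plates, t_hr = 10)
  for (cond in c("NR", "DR")) {
    truth <- setNames(sim$truth[[paste0("true_s_", tolower(cond))]],
                      sim$truth$strain_id)
    sub <- sc[sc$condition == cond, ]
    expect_lt(max(abs(sub$s - truth[sub$strain_id])), 1e-6)
  }
})

test_that("standard errors do not differ between phenotype classes", {
  # noise is class-independent, so the se_s distributions must agree
  cfg <- sim_config(seed = 14, n_mutants = 250, n_wt_replicates = 20)
  sim <- simulate_screen(cfg, conditions = "NR")
  sc <- score_screen(sim$plates)
  cls <- setNames(sim$truth$class, sim$truth$strain_id)[sc$strain_id]
  hit <- sc$se_s[cls %in% c("short", "long")]
  non <- sc$se_s[cls == "neutral"]
  expect_gt(wilcox.test(hit, non)$p.value, 0.05)
})

test_that("qc_filter applies the signal, saturation and age-count rules", {
  cfg <- sim_config(seed = 6, n_mutants = 10, n_wt_replicates = 5)
  sim <- simulate_screen(cfg, conditions = "NR")
  plates <- sim$plates
  # cripple one strain's fluorescence to the floor
  dim_id <- "MUT_0001"
  sel <- plates$strain_id == dim_id
  plates$rfp[sel] <- plates$rfp[sel] * 1e-4
  sc <- score_screen(plates)
  sc <- qc_filter(sc, plates, floor = 1, signal_mult = 5)
  expect_false(sc$qc_pass[sc$strain_id == dim_id])
  # WT replicates sail through on simulated data
  expect_true(all(sc$qc_pass[grepl("^WT_", sc$strain_id)]))

  # a strain with only two usable ages is excluded
  two_age <- plates[plates$strain_id == "MUT_0002" &
                      plates$age_days %in% c(3, 5), ]
  sc2 <- score_screen(rbind(plates[plates$strain_id == "WT_001", ], two_age))
  expect_false(sc2$qc_pass[sc2$strain_id == "MUT_0002"])
})
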