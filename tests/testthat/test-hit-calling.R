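test_that("the WT null is the sample mean and sd", {
  null <- build_null(c(-0.01, 0, 0.01))
  expect_equal(null$mu, 0)
  expect_equal(null$sigma, 0.01)
  expect_equal(null$n, 3)
  expect_error(build_null(c(0.02)), ">= 2")
  expect_error(build_null(rep(0.3, 5)), "zero standard deviation")
})

test_that("simulated WT survival coefficients centre on zero", {
  cfg <- sim_config(seed = 21, n_mutants = 0, n_wt_replicates = 264)
  sim <- simulate_screen(cfg, conditions = "NR")
  sc <- score_screen(sim$plates)
  null <- build_null(sc$s)
  expect_lt(abs(null$mu), 3 * null$sigma / sqrt(264))
})

test_that("z-scores, p-values and BH calls follow the step-up rule", {
  null <- structure(list(mu = 0, sigma = 0.01, n = 100), class = "wt_null")
  sc <- data.frame(strain_id = sprintf("m%d", 1:5), condition = "NR",
                   s = c(-0.03, 0, 0.05, -0.001, 0.002),
                   se_s = 0.001, n_ages = 10, intercept = 0,
                   residual_scale = 0.01, qc_pass = TRUE)
  calls <- call_phenotypes(sc, null, fdr = 0.05)
  expect_equal(calls$z[1], -3)
  expect_equal(calls$p[2], 1)
  expect_equal(calls$call[2], "neutral")
  expect_equal(calls$call[1], "short_lived")
  expect_equal(calls$call[3], "long_lived")

  # hand-checked BH boundary: p = (0.01, 0.02, 0.03, 0.04, 0.2) at 5% FDR
  # rejects the first four (p_(i) <= i/5 * 0.05 holds through i = 4)
  p <- c(0.01, 0.02, 0.03, 0.04, 0.2)
  expect_identical(chronoscreen:::bh_reject(p, 0.05),
                   c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # and the same decision reaches the calls away from the knife edge
  z <- qnorm(c(0.009, 0.019, 0.029, 0.039, 0.2) / 2)
  sc2 <- data.frame(strain_id = sprintf("m%d", 1:5), condition = "NR",
                    s = z * null$sigma, se_s = 0.001, n_ages = 10,
                    intercept = 0, residual_scale = 0.01, qc_pass = TRUE)
  calls2 <- call_phenotypes(sc2, null, fdr = 0.05)
  expect_equal(calls2$q, p.adjust(calls2$p, "BH"), tolerance = 1e-12)
  expect_equal(calls2$call, c(rep("short_lived", 4), "neutral"))
})

test_that("LE is the exact ratio with its identities and monotonicity", {
  expect_equal(compute_le(0.2, 0.2), 1)
  expect_equal(compute_le(0, -0.1), 0.9)
  expect_equal(compute_le(-0.5, 0), 2.0)
  expect_warning(le <- compute_le(-1.2, 0), "undefined")
  expect_true(is.na(le))
  # strictly increasing in s_dr at fixed s_nr
  s_dr <- seq(-0.5, 0.5, by = 0.05)
  expect_true(all(diff(compute_le(rep(0.1, length(s_dr)), s_dr)) > 0))
})

test_that("LE calling applies the null, the stringency filter and categories", {
  mk_calls <- function(ids, calls) {
    data.frame(strain_id = ids, condition = "X", s = 0, call = calls)
  }
  null <- build_null(c(rnorm(50, 1, 0.01)))
  le_tab <- data.frame(strain_id = c("a", "b", "c", "d"),
                       le = c(0.8, 1.25, 0.8, 1.0))
  nr <- mk_calls(c("a", "b", "c", "d"),
                 c("long_lived", "neutral", "neutral", "neutral"))
  dr <- mk_calls(c("a", "b", "c", "d"),
                 c("neutral", "short_lived", "neutral", "neutral"))
  res <- call_le(le_tab, null, nr, dr, fdr = 0.05)
  expect_equal(res$class[res$strain_id == "a"], "diminished")
  expect_equal(res$class[res$strain_id == "b"], "enhanced")
  # significant LE but neutral in both conditions -> demoted to ns
  expect_equal(res$class[res$strain_id == "c"], "ns")
  expect_equal(res$class[res$strain_id == "d"], "ns")
  expect_equal(res$category[res$strain_id == "a"],
               "diminished | long_lived | neutral")
  # a strain missing one condition is excluded with a warning
  le_tab2 <- rbind(le_tab, data.frame(strain_id = "e", le = 0.5))
  expect_warning(res2 <- call_le(le_tab2, null, nr, dr), "excluded")
  expect_false("e" %in% res2$strain_id)
})

test_that("every qc-passing strain gets exactly one call and one LE class", {
  cfg <- sim_config(seed = 10, n_mutants = 60, n_wt_replicates = 40)
  sim <- simulate_screen(cfg)
  sc <- qc_filter(score_screen(sim$plates), sim$plates)
  wt_ids <- sim$truth$strain_id[sim$truth$is_wt]
  calls <- list()
  for (cond in c("NR", "DR")) {
    sub <- sc[sc$condition == cond, ]
    calls[[cond]] <- call_phenotypes(
      sub, build_null(sub$s[sub$strain_id %in% wt_ids & sub$qc_pass]))
  }
  for (cond in c("NR", "DR")) {
    expect_true(all(calls[[cond]]$call %in%
                      c("short_lived", "long_lived", "neutral")))
    expect_false(anyDuplicated(calls[[cond]]$strain_id) > 0)
  }
  shared <- intersect(calls$NR$strain_id, calls$DR$strain_id)
  le_tab <- data.frame(
    strain_id = shared,
    le = compute_le(setNames(calls$NR$s, calls$NR$strain_id)[shared],
                    setNames(calls$DR$s, calls$DR$strain_id)[shared]))
  null <- build_null(wt_le_values(calls$NR, calls$DR,
                                  intersect(wt_ids, shared)))
  res <- call_le(le_tab[!le_tab$strain_id %in% wt_ids, ], null,
                 calls$NR, calls$DR)
  expect_true(all(res$class %in% c("diminished", "enhanced", "ns")))
  expect_true(all(table(res$strain_id) == 1))
})

test_that("WT replicate LE values are overwhelmingly non-significant", {
  cfg <- sim_config(seed = 17, n_mutants = 0, n_wt_replicates = 200)
  sim <- simulate_screen(cfg)
  sc <- score_screen(sim$plates)
  nr <- sc[sc$condition == "NR", ]
  dr <- sc[sc$condition == "DR", ]
  ids <- nr$strain_id
  # split WT replicates: half build the null, half are scored against it
  null_ids <- ids[seq(1, length(ids), by = 2)]
  test_ids <- setdiff(ids, null_ids)
  null <- build_null(wt_le_values(nr, dr, null_ids))
  le <- compute_le(setNames(nr$s, nr$strain_id)[test_ids],
                   setNames(dr$s, dr$strain_id)[test_ids])
  z <- (le - null$mu) / null$sigma
  q <- p.adjust(2 * pnorm(-abs(z)), "BH")
  expect_gte(mean(q > 0.05), 0.95)
})

test_that("cross-screen LE recomputation detects a planted diminished set", {
  set.seed(77)
  n <- 550
  ids <- sprintf("g%03d", seq_len(n))
  s_alt <- rnorm(n, 0, 0.01)
  s_dr <- rnorm(n, 0, 0.01)
  planted <- ids[1:50]
  s_dr[1:50] <- s_dr[1:50] - 0.1          # LE shifted down by ~0.1
  dr_tab <- data.frame(strain_id = ids, s = s_dr)
  alt_tab <- data.frame(strain_id = ids, s = s_alt)
  res <- cross_reference_le(dr_tab, alt_tab, planted, alternative = "less")
  expect_lt(res$p_value, 0.01)
  expect_equal(res$n_set, 50)
  expect_error(cross_reference_le(dr_tab, alt_tab, character()), "empty")
  expect_error(cross_reference_le(dr_tab[1:5, ], alt_tab[1:5, ], planted),
               "fewer than 10")
})

test_that("identical reference screens reproduce the original LE", {
  tab <- data.frame(strain_id = sprintf("g%d", 1:20),
                    s = seq(-0.05, 0.05, length.out = 20))
  res <- cross_reference_le(tab, tab, gene_set = tab$strain_id[1:5])
  expect_equal(res$le$le_alt, compute_le(tab$s, tab$s))
  expect_equal(res$le$le_alt, rep(1, 20))
})
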