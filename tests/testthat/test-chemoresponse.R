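test_that("vehicle-relative survival averages replicates correctly", {
  plate <- data.frame(
    condition = "mimic",
    dose_nM = rep(c(0, 30), each = 3),
    bio_rep = rep(1:3, 2),
    tech_rep = 1,
    signal = c(1, 1, 1, 0.35, 0.40, 0.45)
  )
  rs <- relative_survival(plate, "mimic")
  at30 <- rs$curve[rs$curve$dose_nM == 30, ]
  expect_equal(at30$mean_rel, 0.40)
  expect_equal(at30$sd_rel, 0.05)
  expect_equal(rs$curve$mean_rel[rs$curve$dose_nM == 0], 1)
  # technical replicates are averaged before normalization
  plate2 <- rbind(plate, transform(plate, tech_rep = 2, signal = signal * 1.1))
  rs2 <- relative_survival(plate2, "mimic")
  expect_equal(rs2$curve$mean_rel, rs$curve$mean_rel, tolerance = 1e-10)
  expect_error(relative_survival(plate, "absent"), "absent")
  plate$signal[1] <- 0
  plate_neg <- plate[plate$bio_rep == 1, ]
  expect_error(relative_survival(plate_neg, "mimic"), "positive")
})

test_that("control-transfection ratio cancels per-replicate scale", {
  surv_fun <- function(g) {
    base <- ifelse(g$condition == "mimic", 1 - 0.5 * (g$dose_nM > 0) * 0.8,
                   1 - 0.6 * (g$dose_nM > 0))
    base * ifelse(g$bio_rep == 2, 3.7, 1)  # arbitrary per-replicate units
  }
  plate <- make_plate(c("mimic", "control"), c(0, 30), bio_reps = 2, surv_fun)
  rs_m <- relative_survival(plate, "mimic")
  rs_c <- relative_survival(plate, "control")
  ratio <- relative_to_control(rs_m, rs_c)
  at30 <- ratio$per_rep[ratio$per_rep$dose_nM == 30, ]
  expect_equal(at30$ratio, rep(0.6 / 0.4, 2))  # resistance, units cancelled
  expect_equal(ratio$per_rep$ratio[ratio$per_rep$dose_nM == 0], rep(1, 2))
  # mismatched dose grids error
  rs_c2 <- rs_c
  rs_c2$per_rep <- rs_c2$per_rep[rs_c2$per_rep$dose_nM != 30, ]
  expect_error(relative_to_control(rs_m, rs_c2), "dose grids")
})

test_that("paired one-tailed t matches stats::t.test and the permutation oracle", {
  x <- c(0.60, 0.55, 0.62)
  y <- c(0.50, 0.48, 0.51)
  res <- paired_t_one_tailed(x, y, "greater")
  expect_equal(res$statistic, 7.765, tolerance = 1e-3)
  expect_equal(res$df, 2)
  expect_lt(res$p_value, 0.01)
  # direction swap maps p to 1 - p
  res_less <- paired_t_one_tailed(x, y, "less")
  expect_equal(res_less$p_value, 1 - res$p_value)
  # identical vectors are degenerate at p = 0.5
  same <- paired_t_one_tailed(x, x, "greater")
  expect_true(same$degenerate)
  expect_equal(same$p_value, 0.5)
  expect_equal(same$statistic, 0)
  # constant nonzero differences resolve by sign
  shift <- paired_t_one_tailed(x + 0.1, x, "greater")
  expect_true(shift$degenerate)
  expect_equal(shift$p_value, 0)
  # sign-flip permutation agreement on random paired samples (n <= 6)
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    a <- rnorm(n, 0.6, 0.1)
    b <- a - rnorm(n, 0.05, 0.05)
    t_p <- paired_t_one_tailed(a, b, "greater")$p_value
    perm_p <- oracle_paired_perm_p(a, b, "greater")
    # exact permutation p is discrete on 2^n points; agree within its grain
    expect_lt(abs(t_p - perm_p), 2 / 2^n + 0.05)
  }
  expect_error(paired_t_one_tailed(1:3, 1:4), "equal length")
})

test_that("surviving fraction is the plating-efficiency ratio", {
  sf <- surviving_fraction(30, 100, 60, 100)
  expect_equal(sf$surviving_fraction, 0.5)
  expect_equal(sf$pe_vehicle, 0.6)
  expect_equal(surviving_fraction(60, 100, 60, 100)$surviving_fraction, 1)
  # equal proportional scaling of seeded/colony counts leaves SF unchanged
  expect_equal(surviving_fraction(60, 200, 120, 400)$surviving_fraction,
               surviving_fraction(30, 100, 30, 100)$surviving_fraction * 1)
  expect_error(surviving_fraction(10, 100, 0, 100), "undefined")
})

test_that("IC estimation interpolates on log dose without extrapolation", {
  expect_equal(estimate_ic(c(1, 100), c(1, 0), ic = 50), 10)
  # exact grid hit returns the observed dose
  expect_equal(estimate_ic(c(10, 30, 90), c(0.9, 0.5, 0.1), ic = 50), 30)
  expect_error(estimate_ic(c(1, 10), c(1, 0.8), ic = 50), "outside")
  # monotonicity: a uniformly more resistant curve has a larger IC50
  doses <- c(1, 3, 10, 30, 100, 300)
  s1 <- 1 / (1 + doses / 20)
  s2 <- 1 / (1 + doses / 40)
  expect_gt(estimate_ic(doses, s2), estimate_ic(doses, s1))
  # IC25 < IC50 < IC75 on a decreasing curve
  ics <- sapply(c(25, 50, 75), function(x) estimate_ic(doses, s1, x))
  expect_true(all(diff(ics) > 0))
})

test_that("logistic-simulated IC50s are recovered within 10%", {
  true_ic50 <- 50
  doses <- c(0, 2, 8, 25, 80, 250, 800)
  sim <- sim_viability(c(line = true_ic50), doses = doses, hill = 1.3,
                       noise_cv = 0, seed = 41)
  rs <- relative_survival(sim$plate, "line")
  est <- estimate_ic(rs$curve$dose_nM, rs$curve$mean_rel, ic = 50)
  expect_equal(est, true_ic50, tolerance = 0.10)
})

test_that("resistance ratio summarizes IC50 shifts", {
  expect_equal(resistance_ratio(25, 2), 12.5)
  expect_equal(resistance_ratio(3, 3), 1)
  expect_equal(resistance_ratio(2, 25), 1 / resistance_ratio(25, 2))
  expect_error(resistance_ratio(-1, 2))
})
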