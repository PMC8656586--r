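test_that("global-mean normalization centres on detected miRNAs only", {
  expect_equal(normalize_sample(c(24, 26)), c(-1, 1))
  expect_equal(normalize_sample(c(20, 30, NA)), c(-5, 5, NA))
  # shift invariance of the centred values
  ct <- c(22.1, 25.7, 31.2, NA, 28.4)
  expect_equal(normalize_sample(ct + 3.7), normalize_sample(ct) + 0 * ct)
  expect_error(normalize_sample(c(NA_real_, NA_real_), "case-2/pre"),
               "case-2/pre")
})

test_that("signed-fold convention and its inverse behave as documented", {
  expect_equal(signed_fold(0.5), -2)
  expect_equal(signed_fold(1), 1)
  expect_equal(signed_fold(3.46), 3.46)
  expect_error(signed_fold(-0.1), "positive")
  expect_error(signed_fold(0), "positive")
  # round trip and antisymmetry over a grid of ratios
  r <- c(0.01, 0.2, 0.5, 0.99, 1, 1.3, 2, 50)
  expect_equal(fold_to_ratio(signed_fold(r)), r)
  r2 <- r[r != 1]
  expect_equal(signed_fold(1 / r2), -signed_fold(r2))
  expect_error(fold_to_ratio(0.5), "fold")
})

test_that("delta-delta Ct folds match first-principles recomputation", {
  set.seed(42)
  for (rep in 1:5) {
    pre <- runif(3, 20, 32)
    post <- runif(3, 20, 32)
    ct <- data.frame(
      mirna_id = rep(c("a", "b", "c"), 2),
      case_id = "case-1",
      timepoint = rep(c("pre", "post"), each = 3),
      ct = c(pre, post)
    )
    folds <- ddct_folds(ct)
    expect_equal(folds$ratio, oracle_ddct_case(pre, post)[match(folds$mirna_id, c("a", "b", "c"))])
  }
})

test_that("simple delta-delta Ct arithmetic gives the expected folds", {
  # two miRNAs; reference miRNA constant so the target carries the change
  ct <- data.frame(
    mirna_id = rep(c("target", "ref"), 2),
    case_id = "case-1",
    timepoint = rep(c("pre", "post"), each = 2),
    ct = c(26, 24, 25, 24)
  )
  f <- ddct_folds(ct)
  tgt <- f[f$mirna_id == "target", ]
  # ddCt = (25 - 24.5) - (26 - 25) = -0.5 -> ratio 2^0.5
  expect_equal(tgt$ratio, 2^0.5)
  expect_false(tgt$is_estimate)
})

test_that("pre/post swap inverts every ratio", {
  ct <- sim_ct_arrays(n_mirnas = 30, n_pairs = 2, n_dropout_mirnas = 0,
                      planted_ratios = c("miR-sim-001" = 2), seed = 7)
  swapped <- ct
  swapped$timepoint <- ifelse(ct$timepoint == "pre", "post", "pre")
  f1 <- ddct_folds(ct)
  f2 <- ddct_folds(swapped)
  expect_equal(f1$ratio * f2$ratio, rep(1, nrow(f1)))
  expect_equal(sign(f1$signed_fold[abs(f1$signed_fold) > 1]),
               -sign(f2$signed_fold[abs(f2$signed_fold) > 1]))
})

test_that("adding a constant to one sample's Cts changes no fold", {
  ct <- sim_ct_arrays(n_mirnas = 25, n_pairs = 2, n_dropout_mirnas = 0, seed = 11)
  shifted <- ct
  pick <- shifted$case_id == "case-1" & shifted$timepoint == "post"
  shifted$ct[pick] <- shifted$ct[pick] + 2.4
  expect_equal(ddct_folds(shifted)$ratio, ddct_folds(ct)$ratio)
})

test_that("single-sided dropout imputes at the detection limit and flags", {
  # detected-only means are 30 in both samples by construction, so the
  # imputed value (post Ct = 40) must not perturb them
  ct <- data.frame(
    mirna_id = rep(c("a", "b", "c"), 2),
    case_id = "case-1",
    timepoint = rep(c("pre", "post"), each = 3),
    ct = c(25, 30, 35, 25, 35, NA)
  )
  f <- ddct_folds(ct, detection_limit_ct = 40)
  est <- f[f$mirna_id == "c", ]
  expect_true(est$is_estimate)
  expect_false(est$is_missing)
  # ddCt = (40 - 30) - (35 - 30) = 5
  expect_equal(est$ratio, 2^-5)
  # an unchanged detected miRNA keeps fold 1
  expect_equal(f$ratio[f$mirna_id == "a"], 1)
  # double dropout is a missing record, not a fold
  ct$ct[3] <- NA
  f2 <- ddct_folds(ct)
  expect_true(f2$is_missing[f2$mirna_id == "c"])
  expect_true(is.na(f2$ratio[f2$mirna_id == "c"]))
})

test_that("mean signed fold averages ratios and excludes estimates", {
  expect_equal(round(mean_signed_fold(c(3.46, 1.84, 1.70, 1.33, 4.50)), 2), 2.57)
  expect_equal(round(mean_signed_fold(c(-2.33, -1.42, -14.4, -1.27, -1.36)), 2), -1.83)
  expect_equal(round(mean_signed_fold(c(1.70, 1.32, 1.11, 1.82, 30),
                                      c(FALSE, FALSE, FALSE, FALSE, TRUE)), 2), 1.49)
  expect_error(mean_signed_fold(c(30, 100), c(TRUE, TRUE)), "non-estimate")
})

test_that("consistency filter demands one direction with |fold| > 1 everywhere", {
  mk <- function(folds, missing = FALSE) {
    data.frame(mirna_id = "m", case_id = paste0("case-", seq_along(folds)),
               signed_fold = folds, is_estimate = FALSE, is_missing = missing)
  }
  expect_equal(consistency_filter(mk(c(2, 3, 1.1, 5, 1.5))), "m")
  expect_equal(consistency_filter(mk(c(2, 3, -1.1, 5, 1.5))), character(0))
  expect_equal(consistency_filter(mk(c(-2, -3, -1.1, -5, -1.5))), "m")
  # a double-undetected case disqualifies
  d <- mk(c(2, 3, 1.1, 5, 1.5)); d$is_missing[3] <- TRUE; d$signed_fold[3] <- NA
  expect_equal(consistency_filter(d), character(0))
})

test_that("magnitude filter is monotone in min_fold and nests in consistency", {
  f <- nac_fold_matrix()
  consistent <- consistency_filter(f)
  expect_length(consistent, 12)
  thresholds <- c(1, 1.1, 1.3, 1.6, 2)
  sets <- lapply(thresholds, function(m) magnitude_filter(f, m, consistent))
  expect_equal(sets[[1]], sort(consistent))     # min_fold 1 keeps all 12
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
  expect_equal(magnitude_filter(f, 1.3, consistent), c("miR-195", "miR-26b"))
  expect_error(magnitude_filter(f, 0.9), "min_fold")
})

test_that("fold summary reproduces the published matched-pair table", {
  s <- fold_summary(nac_fold_matrix(), min_fold = 1.3)
  expect_equal(nrow(s), 12)
  expect_equal(sum(s$direction == "up"), 10)
  expect_equal(sum(s$direction == "down"), 2)
  expect_equal(sort(s$mirna_id[s$passes_filter]), c("miR-195", "miR-26b"))
  expect_equal(round(s$mean_fold[s$mirna_id == "miR-195"], 2), 2.57)
  expect_equal(round(s$mean_fold[s$mirna_id == "miR-26b"], 2), 4.87)
  expect_equal(round(s$mean_fold[s$mirna_id == "miR-10a"], 2), -1.83)
  expect_equal(round(s$mean_fold[s$mirna_id == "miR-365"], 2), -1.55)
  expect_equal(signif(s$mean_fold[s$mirna_id == "miR-483-5p"], 3), 1410)
  expect_equal(round(s$mean_fold[s$mirna_id == "miR-330"], 2), 1.49)
  # deterministic ordering: |mean fold| descending
  expect_equal(s$mirna_id[1], "miR-483-5p")
  expect_true(all(diff(abs(s$mean_fold)) <= 0))
})

test_that("zero-noise planted arrays are recovered exactly", {
  planted <- c("miR-sim-001" = 2, "miR-sim-002" = 0.5)
  ct <- sim_ct_arrays(n_mirnas = 40, n_pairs = 3, planted_ratios = planted,
                      ct_noise_sd = 0, n_dropout_mirnas = 0, seed = 3)
  f <- ddct_folds(ct)
  expect_equal(f$signed_fold[f$mirna_id == "miR-sim-001"], rep(2, 3),
               tolerance = 1e-6)
  expect_equal(f$signed_fold[f$mirna_id == "miR-sim-002"], rep(-2, 3),
               tolerance = 1e-6)
})
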