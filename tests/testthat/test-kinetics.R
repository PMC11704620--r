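test_that("slopes come from OLS in the window, in units per minute", {
  cv <- data.frame(time_min = c(0, 5, 10), value = c(100, 110, 120))
  f <- fit_slope(cv)
  expect_equal(f$slope, 2.0)
  expect_equal(f$r2, 1.0)

  flat <- data.frame(time_min = seq(0, 180, 5), value = 7)
  expect_equal(fit_slope(flat)$slope, 0)

  # window restriction: late points are excluded from the fit
  cv2 <- data.frame(time_min = c(0, 60, 120, 240), value = c(0, 60, 120, 0))
  expect_equal(fit_slope(cv2, window = c(0, 180))$slope, 1)
  expect_error(fit_slope(cv2, window = c(300, 400)), "insufficient")
})

test_that("noisy simulated slopes recover the generating rate", {
  set.seed(5)
  rate <- 3.5
  t <- seq(0, 180, 5)
  reps <- replicate(50, {
    cv <- data.frame(time_min = t, value = 10 + rate * t + rnorm(length(t), 0, 20))
    fit_slope(cv)$slope
  })
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - rate), 3 * se + 1e-6)
})

test_that("endpoints pick the nearest sample, earlier on ties", {
  cv <- data.frame(time_min = seq(0, 180, 5), value = seq(0, 180, 5) * 2)
  expect_equal(endpoint(cv), 360)
  cv2 <- data.frame(time_min = c(175, 185), value = c(1, 2))
  expect_equal(endpoint(cv2), 1)  # equidistant -> earlier sample
  cv3 <- data.frame(time_min = seq(0, 120, 5), value = 1)
  expect_error(endpoint(cv3), "missing endpoint")
})

test_that("equal matched and mismatched signals give a specificity fold of 1", {
  curves <- rbind(flat_curves("mut_act", "mutant_detecting", 500, "crM"),
                  flat_curves("wt_act", "mutant_detecting", 500, "crM"))
  expect_equal(specificity_fold(curves, "crM", "mut_act", "wt_act"), 1.0)
  zero <- rbind(flat_curves("mut_act", "mutant_detecting", 500, "crM"),
                flat_curves("wt_act", "mutant_detecting", 0, "crM"))
  expect_error(specificity_fold(zero, "crM", "mut_act", "wt_act"),
               "undefined ratio")
})

test_that("slope-based specificity fold recovers the simulated rho", {
  # near-linear regime so the slope ratio reflects the rate ratio
  cfg <- sim_config(rng_seed = 8L,
                    curve = list(rate = 5e-4, baseline = 0, noise_sd = 10,
                                 specificity_fold = 6, replicates = 8L))
  plate <- simulate_plate(c(mut_act = 1, wt_act = 0), cfg)
  fold <- specificity_fold(plate$curves, "crMUT", "mut_act", "wt_act",
                           metric = "slope")
  expect_lt(abs(fold - 6) / 6, 0.15)
})

test_that("ratio thresholds classify homozygous, heterozygous and imbalanced", {
  calls <- do.call(rbind, lapply(c(6, 1, 0.05, 0.5), function(r) {
    ratio_score(ratio_fixture(r))
  }))
  expect_equal(calls$call, c("homozygous_mutant", "heterozygous",
                             "homozygous_wt", "heterozygous"))
  expect_equal(calls$imbalance_flag, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(calls$ratio, c(6, 1, 0.05, 0.5))
  expect_equal(calls$est_mut_fraction[2], 0.5)
  expect_equal(calls$est_mut_fraction[4], 1 / 3, tolerance = 1e-12)
  # boundary semantics: at least 5, at or below 0.1
  expect_equal(ratio_score(ratio_fixture(5))$call, "homozygous_mutant")
  expect_equal(ratio_score(ratio_fixture(0.1))$call, "homozygous_wt")
})

test_that("swapping the crRNA labels inverts the ratio and mirrors the calls", {
  swap <- function(curves) {
    r <- curves$role
    curves$role[r == "mutant_detecting"] <- "wt_detecting"
    curves$role[r == "wt_detecting"] <- "mutant_detecting"
    curves
  }
  for (r in c(20, 1, 0.7, 0.05)) {
    fx <- ratio_fixture(r)
    a <- ratio_score(fx)
    b <- ratio_score(swap(fx))
    expect_equal(b$ratio, 1 / a$ratio, tolerance = 1e-12)
    mirrored <- c(homozygous_mutant = "homozygous_wt",
                  heterozygous = "heterozygous",
                  homozygous_wt = "homozygous_mutant")
    expect_equal(b$call, unname(mirrored[a$call]))
  }
})

test_that("estimated mutant fraction rises monotonically with the ratio", {
  ratios <- c(0.05, 0.2, 1, 3, 10)
  fr <- vapply(ratios, function(r) ratio_score(ratio_fixture(r))$est_mut_fraction,
               numeric(1))
  expect_true(all(diff(fr) > 0))
  expect_equal(fr[3], 0.5)
})

test_that("ratio scoring demands both crRNA roles and a nonzero denominator", {
  only_mut <- flat_curves("s", "mutant_detecting", 100)
  expect_error(ratio_score(only_mut), "wt-detecting")
  bad <- rbind(flat_curves("s", "mutant_detecting", 100),
               flat_curves("s", "wt_detecting", 0))
  expect_error(ratio_score(bad), "undefined ratio")
})

test_that("background calls use a 3-SD rule over blank replicates", {
  set.seed(9)
  blank <- do.call(rbind, lapply(1:4, function(r) {
    data.frame(sample = "water", crrna = "none", role = "control",
               replicate = r, time_min = seq(0, 180, 5),
               value = rnorm(37, 100, 5))
  }))
  same <- blank
  same$sample <- "s"
  expect_false(above_background(same, blank))
  strong <- flat_curves("s", "mutant_detecting", 5000)
  expect_true(above_background(strong, blank))
  one_blank <- blank[blank$replicate == 1, ]
  expect_error(above_background(strong, one_blank), "blank replicates")
})
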