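test_that("replicate t interval matches the hand-computed case", {
  ci <- mean_ci(c(1, 2, 3, 4))
  expect_equal(ci$mean, 2.5)
  expect_equal(ci$lower, 0.446, tolerance = 1e-3)
  expect_equal(ci$upper, 4.554, tolerance = 1e-3)

  # agreement with the standard one-sample t machinery
  x <- c(0.3, 0.5, 0.45, 0.62, 0.51)
  tt <- t.test(x)
  ci2 <- mean_ci(x)
  expect_equal(c(ci2$lower, ci2$upper), as.vector(tt$conf.int),
               tolerance = 1e-12)

  expect_equal(mean_ci(rep(3, 4))$lower, 3)
  expect_equal(mean_ci(rep(3, 4))$upper, 3)
  d <- mean_ci(5)
  expect_true(d$degenerate)
  expect_equal(c(d$lower, d$upper), c(5, 5))
  expect_error(mean_ci(numeric(0)), "zero values")
})

test_that("t intervals achieve nominal coverage on normal replicates", {
  set.seed(202)
  nsim <- 1e5; n <- 4
  x <- matrix(rnorm(nsim * n, mean = 10, sd = 2), nrow = n)
  m <- colMeans(x)
  half <- qt(0.975, n - 1) * apply(x, 2, sd) / sqrt(n)
  coverage <- mean(m - half <= 10 & 10 <= m + half)
  expect_equal(coverage, 0.95, tolerance = 0.011)
})

test_that("MOVER-R reproduces closed-form hand cases", {
  est <- mover_r_ratio(interval(10, 8, 12), interval(5, 4, 6))
  expect_equal(est$ratio, 2)
  expect_equal(est$lower, 1.5, tolerance = 1e-3)
  expect_equal(est$upper, 2.667, tolerance = 1e-3)

  # exact denominator: reduces to simple interval division
  est2 <- mover_r_ratio(interval(2, 1, 3), interval(2, 2, 2))
  expect_equal(est2$ratio, 1)
  expect_equal(est2$lower, 0.5, tolerance = 1e-12)
  expect_equal(est2$upper, 1.5, tolerance = 1e-12)

  expect_error(mover_r_ratio(interval(2, 1, 3), interval(1, -0.5, 2.5)),
               "contains 0")
  expect_error(mover_r_ratio(interval(2, 1, 3), interval(1, 0.5, 1.5, level = 0.9)),
               "different levels")
})

test_that("LOQ censoring uses a strict mean comparison by default", {
  m <- measurement_set("Am", "tubing_only", c(2e-9, 3e-9, 4e-9, 3e-9),
                       loq = 5e-9)
  expect_equal(censor_by_loq(m)$censored, "below_loq")

  at <- measurement_set("Am", "tubing_only", rep(5e-9, 4), loq = 5e-9)
  expect_equal(censor_by_loq(at)$censored, "none")

  # replicate-level rule censors when any single replicate dips below
  mixed <- measurement_set("Am", "tubing_only", c(4e-9, 6e-9, 7e-9, 7e-9),
                           loq = 5e-9)
  expect_equal(censor_by_loq(mixed)$censored, "none")
  expect_equal(censor_by_loq(mixed, rule = "any_replicate")$censored,
               "below_loq")

  expect_error(censor_by_loq(measurement_set("Am", "frozen", 1:4)), "no LOQ")
})

test_that("hydrophobic compounds at high tubing sorption censor as expected", {
  # >= 99.2% sorption for the three most hydrophobic compounds at their
  # dosing concentrations, against their assay LOQs
  panel <- builtin_panel()
  mc <- molar_concentration(panel)
  loq <- default_loq_map(panel)
  exp_chain <- 0.25 * 12.7
  for (id in c("Am", "Cl", "Se")) {
    tpsa <- panel$tpsa_nm2[panel$id == id]
    surviving <- mc[[id]] * 0.6 * tpsa^exp_chain
    expect_gte(1 - tpsa^exp_chain, 0.992)
    m <- measurement_set(id, "tubing_only", rep(surviving, 4), loq = loq[[id]])
    expect_equal(censor_by_loq(m)$censored, "below_loq")
  }
})

test_that("area normalization is a power law and composes", {
  r <- interval_to_recovery <- function(ratio, lower, upper) {
    structure(list(compound_id = "X", ratio = ratio, lower = lower,
                   upper = upper, level = 0.95, censored = "none",
                   normalized_area_cm2 = NA_real_),
              class = "recovery_estimate")
  }
  est <- r(0.81, 0.7, 0.9)
  out <- normalize_recovery_area(est, 10, 5)
  expect_equal(out$ratio, 0.9)
  expect_equal(out$lower, 0.7^0.5)
  expect_equal(out$upper, 0.9^0.5)

  # identity and lossless cases
  expect_equal(normalize_recovery_area(est, 10, 10)$ratio, 0.81)
  expect_equal(normalize_recovery_area(r(1, 1, 1), 10, 3)$ratio, 1)

  # composition: 10 -> 5 -> 1 equals 10 -> 1
  two_step <- normalize_recovery_area(normalize_recovery_area(est, 10, 5), 5, 1)
  one_step <- normalize_recovery_area(est, 10, 1)
  expect_equal(two_step$ratio, one_step$ratio, tolerance = 1e-12)
  expect_equal(two_step$lower, one_step$lower, tolerance = 1e-12)

  expect_error(normalize_recovery_area(est, 0, 5), "areas")
  expect_error(normalize_recovery_area(r(0, 0, 0), 10, 5), "zero recovery")
})

test_that("recovery chain decomposes multiplicative losses and telescopes", {
  set.seed(31)
  base <- rnorm(4, 100, 3)
  same <- function(cond) measurement_set("X", cond, base)
  all_one <- recovery_chain(same("device"), same("tubing_only"),
                            same("vessel"), same("frozen"))
  expect_equal(all_one$ratio, rep(1, 3))
  expect_true(all(all_one$censored == "none"))

  # synthetic degradation factor on the vessel condition
  frozen <- measurement_set("X", "frozen", rnorm(4, 100, 2))
  vessel <- measurement_set("X", "vessel", rnorm(4, 70, 2))
  tubing <- measurement_set("X", "tubing_only", rnorm(4, 35, 1.5))
  device <- measurement_set("X", "device", rnorm(4, 30, 1.5))
  chain <- recovery_chain(device, tubing, vessel, frozen)
  vf <- chain[chain$ratio_name == "vessel_over_frozen", ]
  expect_equal(vf$ratio, 0.70, tolerance = 0.1)
  expect_true(vf$lower < vf$ratio && vf$ratio < vf$upper)

  # chain product telescopes to the device/frozen ratio of means exactly
  prod_chain <- prod(chain$ratio)
  expect_equal(prod_chain, mean(device$values) / mean(frozen$values),
               tolerance = 1e-12)
})

test_that("censoring propagates through the chain", {
  frozen <- measurement_set("X", "frozen", c(100, 101, 99, 100), loq = 5)
  vessel <- measurement_set("X", "vessel", c(98, 97, 99, 101), loq = 5)
  tubing <- measurement_set("X", "tubing_only", c(2, 3, 2.5, 2.8), loq = 5)
  device <- measurement_set("X", "device", c(1, 1.2, 0.9, 1.1), loq = 5)
  chain <- recovery_chain(device, tubing, vessel, frozen)

  dt <- chain[chain$ratio_name == "device_over_tubing", ]
  expect_equal(dt$censored, "blocked_denominator")
  expect_true(is.na(dt$ratio))

  tv <- chain[chain$ratio_name == "tubing_over_vessel", ]
  expect_equal(tv$censored, "below_loq")
  expect_equal(tv$lower, 0) # uncapped lower error bar
  expect_false(is.na(tv$ratio))

  expect_error(
    recovery_chain(device, tubing, vessel,
                   measurement_set("Y", "frozen", 1:4)),
    "one compound")
  expect_error(
    recovery_chain(device, tubing, vessel,
                   measurement_set("X", "frozen", 1:4, units = "c_norm")),
    "unit mismatch")
})

test_that("null device sorption yields CIs enveloping a recovery of 1", {
  cfg0 <- generator_config(material_slopes = c(tubing = 0.25, device = 0),
                           seed = 5)
  sim <- simulate_experiment(cfg0)
  res <- analyze_experiment(sim)
  dev <- res$recoveries[res$recoveries$ratio_name == "device_over_tubing" &
                          res$recoveries$censored == "none", ]
  envelops <- dev$lower <= 1 & 1 <= dev$upper
  # per-compound 95% intervals around a true ratio of 1
  expect_gte(mean(envelops), 0.85)
  expect_equal(mean(dev$ratio), 1, tolerance = 0.05)
})
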