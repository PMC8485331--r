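test_that("noiseless power-law data give exact slope, degenerate CI, r = 1", {
  tpsa <- c(0.032, 0.12, 0.36, 0.674, 0.895)
  fit <- fixed_intercept_loglog_fit(tpsa, tpsa^0.25)
  expect_equal(fit$slope, 0.25, tolerance = 1e-12)
  expect_equal(fit$slope_ci, c(0.25, 0.25))
  expect_equal(fit$pearson_r, 1)
})

test_that("fit matches the brute-force normal equations and SE formula", {
  set.seed(91)
  tpsa <- builtin_panel()$tpsa_nm2
  rec <- pmin(tpsa^0.2 * exp(rnorm(length(tpsa), 0, 0.05)), 1.5)
  fit <- fixed_intercept_loglog_fit(tpsa, rec)
  x <- log10(tpsa); y <- log10(rec)
  expect_equal(fit$slope, brute_force_origin_slope(x, y), tolerance = 1e-12)
  se <- brute_force_origin_slope_se(x, y)
  half <- qt(0.975, length(x) - 1) * se
  expect_equal(fit$slope_ci, fit$slope + c(-half, half), tolerance = 1e-9)
  expect_equal(fit$pearson_r, cor(x, y), tolerance = 1e-12)
})

test_that("slope is scale-equivariant under recovery powers", {
  set.seed(14)
  tpsa <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  rec <- tpsa^0.3 * exp(rnorm(5, 0, 0.02))
  f1 <- fixed_intercept_loglog_fit(tpsa, rec)
  f2 <- fixed_intercept_loglog_fit(tpsa, pmin(rec^2, 1.5))
  expect_equal(f2$slope, 2 * f1$slope, tolerance = 1e-9)
})

test_that("degenerate and invalid trend inputs are rejected", {
  expect_error(fixed_intercept_loglog_fit(rep(1, 5), rep(0.9, 5)),
               "undefined")
  expect_error(fixed_intercept_loglog_fit(c(0.1, 0.2), c(0.9, 0.8)),
               "at least 3")
  expect_error(fixed_intercept_loglog_fit(c(0.1, 0.2, 0.3), c(0.9, 1.6, 0.8)),
               "1.5")
  expect_error(fixed_intercept_loglog_fit(c(-0.1, 0.2, 0.3), c(0.9, 0.9, 0.8)),
               "TPSA")
})

test_that("simulated noisy recoveries cover the true slope at nominal rate", {
  tpsa <- builtin_panel()$tpsa_nm2
  covered <- vapply(1:100, function(seed) {
    set.seed(seed + 4000)
    # ratio-of-means noise on n = 4 lognormal replicates, CV 8%
    rec <- vapply(tpsa^0.25, function(mu) {
      mean(mu * rlnorm(4, -0.5 * log(1.0064), sqrt(log(1.0064)))) /
        mean(rlnorm(4, -0.5 * log(1.0064), sqrt(log(1.0064))))
    }, numeric(1))
    f <- fixed_intercept_loglog_fit(tpsa, pmin(rec, 1.5))
    f$slope_ci[1] <= 0.25 && 0.25 <= f$slope_ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("material comparison orders by slope and flags CI overlap", {
  tpsa <- c(0.032, 0.12, 0.36, 0.674, 0.895)
  mk <- function(slope, mat) {
    fixed_intercept_loglog_fit(tpsa, tpsa^slope, material = mat)
  }
  devices <- compare_material_trends(list(
    mk(0.08, "PDMS"), mk(0.06, "OSTE+"), mk(0.02, "PC/PSA")))
  expect_equal(devices$table$material, c("PC/PSA", "OSTE+", "PDMS"))
  tubings <- compare_material_trends(list(
    mk(0.25, "PharMed BPT"), mk(0.28, "Tygon SI"), mk(0.10, "Tygon MHLL")))
  expect_equal(tubings$table$material,
               c("Tygon MHLL", "PharMed BPT", "Tygon SI"))

  single <- compare_material_trends(list(mk(0.1, "solo")))
  expect_equal(nrow(single$table), 1)

  twin <- compare_material_trends(list(mk(0.1, "a"), mk(0.1, "b")))
  expect_true(all(twin$overlap))

  f1 <- mk(0.1, "a"); f2 <- mk(0.1, "b"); f2$norm_area_cm2 <- 10
  expect_error(compare_material_trends(list(f1, f2)), "different areas")
})

test_that("VIP concentrates on the driving descriptor and satisfies its identity", {
  set.seed(77)
  n <- 200
  X <- cbind(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  Xs <- scale(X)
  v <- pls_vip(Xs, Xs[, "signal"], n_components = 1)
  # weight concentrates: the driver approaches sqrt(p) with p = 3
  expect_equal(unname(v$descriptor_scores["signal"]), sqrt(3),
               tolerance = 0.02)
  expect_lt(max(v$descriptor_scores[c("noise1", "noise2")]), 0.35)
  expect_equal(mean(v$descriptor_scores^2), 1, tolerance = 1e-9)

  # identity holds for arbitrary fits and component counts
  set.seed(78)
  X2 <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(NULL, paste0("d", 1:8)))
  y2 <- rnorm(40)
  for (a in c(1, 3, 5)) {
    expect_equal(mean(pls_vip(scale(X2), y2, a)$descriptor_scores^2), 1,
                 tolerance = 1e-9)
  }
})

test_that("VIP is invariant to descriptor column order", {
  set.seed(79)
  X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("d", 1:5)))
  y <- X[, 3] + rnorm(60, 0, 0.2)
  v1 <- pls_vip(scale(X), y, 2)$descriptor_scores
  o <- c(4, 2, 5, 1, 3)
  v2 <- pls_vip(scale(X[, o]), y, 2)$descriptor_scores
  expect_equal(v1[sort(names(v1))], v2[sort(names(v2))], tolerance = 1e-12)
})

test_that("VIP agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(42)
  n <- 30; p <- 6
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("d", 1:p)))
  y <- X[, 2] * 2 + X[, 5] + rnorm(n, sd = 0.3)
  ours <- pls_vip(scale(X), y, n_components = 2)$descriptor_scores
  ref <- mixOmics::vip(mixOmics::pls(X, y, ncomp = 2, scale = TRUE,
                                     mode = "regression"))[, 2]
  expect_equal(ours[names(ref)], ref, tolerance = 1e-9)
})

test_that("log(TPSA) ranks first on TPSA-driven data with correlated log P", {
  panel <- builtin_panel()
  wins <- vapply(1:40, function(seed) {
    set.seed(seed + 900)
    lt <- log10(panel$tpsa_nm2)
    ltz <- (lt - mean(lt)) / sd(lt)
    # a log P surrogate correlated at r = 0.8 with log(TPSA)
    lp <- 0.8 * ltz + sqrt(1 - 0.8^2) * rnorm(18)
    X <- cbind(log_tpsa = lt, log_p = lp,
               hbond_acceptor_count = rnorm(18), polarizability = rnorm(18),
               log_c_over_m = rnorm(18))
    y <- 0.25 * lt + rnorm(18, 0, 0.05)
    v <- pls_vip(scale(X), y, n_components = 1)
    names(v$descriptor_scores)[1] == "log_tpsa"
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("component selection by LOO cross-validation returns a sane count", {
  set.seed(100)
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("d", 1:6)))
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(40, 0, 0.2)
  v <- pls_vip(scale(X), y)
  expect_gte(v$n_components, 1)
  expect_lte(v$n_components, 6)
  expect_gt(v$y_variance_explained, 0.7)
  expect_error(pls_vip(scale(X), y, n_components = 20), "rank")
})
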