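# Independent numerical oracles used across the test files.

# Finite-difference uptake into a semi-infinite slab whose interface is held
# at the partition equilibrium P * C0 (the sorption model's physics: liquid
# depletion neglected). Explicit FTCS scheme; returns the loss fraction
# uptake_per_area * A / (V * C0) = uptake * R.
fd_sorption_loss <- function(ratio_R_mm, log_p, D_cm2_s, t_h, nx = 300) {
  P <- 10^log_p
  t <- t_h * 3600
  R_cm <- ratio_R_mm * 10
  L <- 8 * sqrt(D_cm2_s * t) # depth; c(L)/c(0) = erfc(4) ~ 1.5e-8
  dx <- L / nx
  dt <- 0.4 * dx^2 / D_cm2_s
  nt <- ceiling(t / dt)
  dt <- t / nt
  lam <- D_cm2_s * dt / dx^2
  c <- numeric(nx + 1)
  c[1] <- P
  for (s in seq_len(nt)) {
    c[2:nx] <- c[2:nx] + lam * (c[3:(nx + 1)] - 2 * c[2:nx] + c[1:(nx - 1)])
  }
  uptake <- (sum(c) - (c[1] + c[nx + 1]) / 2) * dx # trapezoid, C0 = 1
  uptake * R_cm
}

# Perimeter-averaged wall shear stress in a rectangular duct from the exact
# series solution: flow resistance from the Fourier series for Q(G), then
# the force balance tau_avg = G * w * h / (2 (w + h)). Inputs in mPa.s,
# mL/h, mm; output in dyne/cm^2.
duct_series_wall_shear <- function(viscosity_mPas, flow_mL_h, w_mm, h_mm,
                                   nterms = 199) {
  mu <- viscosity_mPas * 1e-3          # Pa.s
  Q <- flow_mL_h * 1e-6 / 3600         # m^3/s
  a <- h_mm / 2 * 1e-3                 # half-height, m
  b <- w_mm / 2 * 1e-3                 # half-width, m
  i <- seq(1, nterms, by = 2)
  series <- sum(tanh(i * pi * b / (2 * a)) / i^5)
  G <- Q * 3 * mu / (4 * b * a^3 * (1 - 192 * a / (pi^5 * b) * series))
  tau_Pa <- G * (w_mm * h_mm * 1e-6) / (2 * (w_mm + h_mm) * 1e-3)
  tau_Pa * 10
}

# Through-origin least squares by direct summation.
brute_force_origin_slope <- function(x, y) sum(x * y) / sum(x * x)

brute_force_origin_slope_se <- function(x, y) {
  s <- brute_force_origin_slope(x, y)
  sqrt(sum((y - s * x)^2) / ((length(x) - 1) * sum(x^2)))
}

# Bisection inversion of the calibration forward model.
bisect_invert <- function(signal, fit, lo = 0, hi = 10, iters = 200) {
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (forward_signal(mid, fit) < signal) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Interval-estimate constructor for hand-specified intervals.
interval <- function(mean, lower, upper, level = 0.95, n = 4L) {
  structure(list(mean = mean, lower = lower, upper = upper, level = level,
                 n = n, degenerate = FALSE), class = "interval_estimate")
}

# A complete synthetic extended-descriptor table for a panel (values drawn
# once per call; descriptor semantics are irrelevant to the algebra under
# test, only the names and shapes matter).
synthetic_descriptors <- function(panel, missing_log_s_for = character(0)) {
  vocab <- setdiff(descriptor_vocabulary(), c("log_tpsa", "log_c_over_m"))
  n <- nrow(panel)
  d <- as.data.frame(lapply(stats::setNames(vocab, vocab),
                            function(nm) stats::rnorm(n)))
  d$molar_mass <- panel$molar_mass_Da
  d$log_p <- panel$log_p
  d$hbond_donor_count <- panel$hbd
  d$log_s[panel$id %in% missing_log_s_for] <- NA_real_
  cbind(id = panel$id, d)
}
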