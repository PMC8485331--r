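# Synthetic experiment generator. The generator encodes the statistical
# structure the analysis assumes -- multiplicative losses along the
# frozen -> vessel -> tubing -> device chain, TPSA power-law sorption,
# lognormal replicate noise, per-assay molar LOQs -- with ground truth
# recoverable by the estimator chain.

#' Default molar LOQ map for the built-in panel
#'
#' LC/MS assay limits of quantification: 1 nM for Ha, Pa, Ri, Se; 0.5 uM for
#' La, Li, Ru, Zo; 5 nM for Am, No, Cl, Ci, Fl, Vo, Me. Fluorophores are
#' quantified by plate-reader fluorescence; their effective molar limit is
#' taken as 1% of the nominal dosing concentration (a typical calibrated
#' dynamic range), so they censor only under extreme loss.
#'
#' @param panel Panel data.frame (default [builtin_panel()]).
#' @return Named numeric vector of LOQs (mol/L) keyed by compound id.
#' @export
default_loq_map <- function(panel = builtin_panel()) {
  loq <- c(
    Ha = 1e-9, Pa = 1e-9, Ri = 1e-9, Se = 1e-9,
    La = 5e-7, Li = 5e-7, Ru = 5e-7, Zo = 5e-7,
    Am = 5e-9, No = 5e-9, Cl = 5e-9, Ci = 5e-9, Fl = 5e-9, Vo = 5e-9,
    Me = 5e-9
  )
  fluor <- panel$id[panel$class == "fluorophore"]
  if (length(fluor) > 0) {
    molar <- molar_concentration(panel[panel$id %in% fluor, , drop = FALSE])
    loq <- c(loq, 0.01 * molar)
  }
  loq[intersect(panel$id, names(loq))]
}

#' Generator configuration
#'
#' Defaults emulate the study conditions the analysis is built for: the
#' built-in 18-compound panel; a tubing-only control circuit of 79 cm of
#' 0.51 mm ID pump tubing (12.7 cm^2 wetted area) with a true
#' hydrophobicity slope of 0.25 per cm^2; a 1 cm^2 low-sorbing device at
#' slope 0.08 per cm^2; 40% thermal degradation (survival 0.6) for the three
#' degradation-prone compounds Am, Cl and Se; lognormal replicate noise at
#' 8% CV; n = 4 replicates per condition; and the per-assay molar LOQs of
#' [default_loq_map()].
#'
#' @param panel Compound panel data.frame.
#' @param material_slopes Named true log-log TPSA slopes at 1 cm^2,
#'   `c(tubing = ..., device = ...)`, >= 0.
#' @param material_areas Named exposed areas (cm^2).
#' @param degradation Named vessel survival fractions in (0, 1] for the
#'   degradation-prone compounds (all others survive fully).
#' @param noise_cv Lognormal replicate coefficient of variation (>= 0).
#' @param n_replicates Replicates per condition (>= 1).
#' @param loq Named molar LOQ vector (see [default_loq_map()]).
#' @param seed Integer seed recorded in all outputs.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(panel = builtin_panel(),
                             material_slopes = c(tubing = 0.25, device = 0.08),
                             material_areas = c(tubing = 12.7, device = 1),
                             degradation = c(Am = 0.6, Cl = 0.6, Se = 0.6),
                             noise_cv = 0.08,
                             n_replicates = 4,
                             loq = default_loq_map(panel),
                             seed = 1L) {
  validate_panel(panel)
  if (any(material_slopes < 0)) stop("slopes must be >= 0")
  if (!all(c("tubing", "device") %in% names(material_slopes)) ||
      !all(c("tubing", "device") %in% names(material_areas))) {
    stop("material_slopes and material_areas need 'tubing' and 'device' entries")
  }
  if (length(degradation) > 0) {
    unknown <- setdiff(names(degradation), panel$id)
    if (length(unknown) > 0) {
      stop("degradation map names unknown compound(s): ",
           paste(unknown, collapse = ", "))
    }
    if (any(degradation <= 0 | degradation > 1)) {
      stop("degradation survival fractions must lie in (0, 1]")
    }
  }
  unknown_loq <- setdiff(names(loq), panel$id)
  if (length(unknown_loq) > 0) {
    stop("loq map names unknown compound(s): ",
         paste(unknown_loq, collapse = ", "))
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(
    list(panel = panel, material_slopes = material_slopes,
         material_areas = material_areas, degradation = degradation,
         noise_cv = noise_cv, n_replicates = as.integer(n_replicates),
         loq = loq, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' True condition means implied by a generator configuration
#'
#' The noise-free multiplicative chain: frozen = nominal molar concentration;
#' vessel = frozen x survival; tubing_only = vessel x TPSA^(slope_t x A_t);
#' device = tubing_only x TPSA^(slope_d x A_d).
#'
#' @param cfg A [generator_config()].
#' @return data.frame: `compound_id`, `tpsa_nm2`, and the four true means
#'   (mol/L).
#' @export
generator_truth <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  panel <- cfg$panel
  c0 <- molar_concentration(panel)
  surv <- rep(1, nrow(panel))
  names(surv) <- panel$id
  surv[names(cfg$degradation)] <- cfg$degradation
  exp_t <- cfg$material_slopes[["tubing"]] * cfg$material_areas[["tubing"]]
  exp_d <- cfg$material_slopes[["device"]] * cfg$material_areas[["device"]]
  frozen <- unname(c0)
  vessel <- frozen * unname(surv)
  tubing <- vessel * panel$tpsa_nm2^exp_t
  device <- tubing * panel$tpsa_nm2^exp_d
  data.frame(compound_id = panel$id, tpsa_nm2 = panel$tpsa_nm2,
             frozen = frozen, vessel = vessel, tubing_only = tubing,
             device = device, stringsAsFactors = FALSE)
}

#' Simulate a complete endpoint sorption experiment
#'
#' Draws `n_replicates` lognormal replicates (mean equal to the true
#' condition mean, coefficient of variation `noise_cv`) for every compound
#' under the four conditions frozen / vessel / tubing_only / device. Output
#' is deterministic given the config (the seed is part of the config):
#' identical configs give identical tables.
#'
#' @param cfg A [generator_config()].
#' @return Long data.frame with columns `compound_id`, `condition`,
#'   `replicate`, `value` (mol/L), `loq`, `tpsa_nm2`; attributes `config`
#'   (the full generator config) and `truth` ([generator_truth()]).
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  truth <- generator_truth(cfg)
  conditions <- c("frozen", "vessel", "tubing_only", "device")
  n <- cfg$n_replicates
  # lognormal with E[X] = mu and CV = noise_cv
  sdlog <- sqrt(log(1 + cfg$noise_cv^2))

  set.seed(cfg$seed)
  rows <- vector("list", nrow(truth) * length(conditions))
  k <- 0
  for (i in seq_len(nrow(truth))) {
    id <- truth$compound_id[i]
    loq_i <- if (id %in% names(cfg$loq)) cfg$loq[[id]] else NA_real_
    for (cond in conditions) {
      mu <- truth[[cond]][i]
      values <- if (sdlog == 0) rep(mu, n) else {
        mu * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      }
      k <- k + 1
      rows[[k]] <- data.frame(
        compound_id = id, condition = cond, replicate = seq_len(n),
        value = values, loq = loq_i, tpsa_nm2 = truth$tpsa_nm2[i],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- cfg
  attr(out, "truth") <- truth
  out
}

#' Simulate plate-reader fluorescence data through a calibration model
#'
#' Emits a serial-dilution calibration series and per-sample signals obtained
#' by pushing simulated fluorophore concentrations through
#' [forward_signal()] with multiplicative noise, for testing the
#' fit -> invert -> recovery path end to end.
#'
#' @param cfg A [generator_config()]; only fluorophore-class compounds are
#'   used.
#' @param fit A [calibration_fit()] acting as the true instrument response.
#' @param dilution_levels Normalized concentrations of the calibration
#'   series (default two-fold series 1 ... 1/64 plus blank).
#' @param signal_cv Multiplicative signal noise CV (default 0.01).
#' @return List with `calibration` (data.frame `c_norm`, `signal`) and
#'   `samples` (data.frame `compound_id`, `condition`, `replicate`,
#'   `c_norm_true`, `signal`).
#' @export
simulate_fluorescence <- function(cfg, fit,
                                  dilution_levels = c(1 / 2^(0:6), 0),
                                  signal_cv = 0.01) {
  stopifnot(inherits(cfg, "generator_config"),
            inherits(fit, "calibration_fit"))
  sim <- simulate_experiment(cfg)
  fluor <- cfg$panel$id[cfg$panel$class == "fluorophore"]
  nominal <- molar_concentration(cfg$panel)

  sdlog <- sqrt(log(1 + signal_cv^2))
  noisy <- function(x) {
    if (sdlog == 0) x else {
      x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
  }

  calib <- data.frame(
    c_norm = dilution_levels,
    signal = noisy(forward_signal(dilution_levels, fit))
  )

  rows <- sim[sim$compound_id %in% fluor, , drop = FALSE]
  c_norm_true <- rows$value / nominal[rows$compound_id]
  samples <- data.frame(
    compound_id = rows$compound_id, condition = rows$condition,
    replicate = rows$replicate, c_norm_true = c_norm_true,
    signal = noisy(forward_signal(c_norm_true, fit)),
    stringsAsFactors = FALSE
  )
  list(calibration = calib, samples = samples)
}
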