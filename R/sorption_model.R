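# Partition-diffusion prediction of compound recovery after PDMS exposure.
#
# The model treats the elastomer as a semi-infinite absorbing slab: the
# well-mixed liquid holds concentration C0, the slab surface is pinned at the
# partition equilibrium P*C0, and uptake follows 1-D diffusion. Because the
# liquid-side depletion is deliberately neglected (no saturation), predicted
# loss grows without bound as sqrt(t) and is clamped by a max(., 0) on the
# recovery. The clamp and the neglect of depletion are acknowledged model
# shortcomings, not numerical conveniences.

#' Reference diffusivities for PDMS
#'
#' Reads a CSV table of reference molecules with measured diffusion
#' coefficients inside PDMS (`name,molar_mass_Da,D_cm2_per_s,source`).
#' The file shipped with the package is a clearly labelled SYNTHETIC stand-in
#' carrying order-of-magnitude values for three fluorophore-class molecules;
#' substitute your own measured table for quantitative work.
#'
#' @param path Path to a reference CSV; default uses the shipped synthetic
#'   stand-in table.
#' @return data.frame with columns `name`, `molar_mass_Da`, `D_cm2_per_s`,
#'   `source`.
#' @export
reference_diffusivities <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_diffusivities_synthetic.csv",
                        package = "chipsorb", mustWork = TRUE)
  }
  refs <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("name", "molar_mass_Da", "D_cm2_per_s")
  if (!all(req %in% names(refs))) {
    stop("reference CSV must have columns ", paste(req, collapse = ", "))
  }
  if (any(refs$D_cm2_per_s <= 0) || any(refs$molar_mass_Da <= 0)) {
    stop("reference diffusivities and molar masses must be > 0")
  }
  refs
}

#' Default mass-scaling exponent for diffusivity transfer
#'
#' The exponent is configuration, not a constant baked into code: it is read
#' from `inst/extdata/diffusivity_config.json`, which documents the choice.
#'
#' @param path Optional path to an alternative JSON config.
#' @return Numeric exponent (> 0).
#' @export
default_mass_exponent <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "diffusivity_config.json",
                        package = "chipsorb", mustWork = TRUE)
  }
  cfg <- jsonlite::read_json(path)
  ex <- cfg$mass_exponent
  if (!is.numeric(ex) || ex <= 0) stop("mass_exponent must be > 0")
  ex
}

#' Estimate PDMS diffusivity of a compound from reference molecules
#'
#' Transfers each reference measurement by the inverse mass-ratio scaling
#' D_i = D_ref * (M_ref / M_i)^exponent, then summarises the spread of the
#' per-reference estimates: `mid` is their geometric mean, `low`/`high` are
#' the minimum and maximum. The spread, not a formal variance, is what the
#' downstream prediction bounds carry, because reference measurements
#' disagree by amounts comparable to the values themselves.
#'
#' @param molar_mass_Da Target compound molar mass (Da).
#' @param refs Reference table as from [reference_diffusivities()].
#' @param exponent Mass-scaling exponent (> 0); see [default_mass_exponent()].
#' @return List with `low`, `mid`, `high` (cm^2/s) and `per_ref` (named
#'   vector of per-reference estimates).
#' @export
estimate_diffusivity <- function(molar_mass_Da, refs,
                                 exponent = default_mass_exponent()) {
  if (!is.data.frame(refs) || nrow(refs) == 0) {
    stop("refs must be a non-empty reference table")
  }
  if (!is.finite(molar_mass_Da) || molar_mass_Da <= 0) {
    stop("molar_mass_Da must be > 0")
  }
  if (exponent < 0) stop("exponent must be >= 0")
  d <- refs$D_cm2_per_s * (refs$molar_mass_Da / molar_mass_Da)^exponent
  names(d) <- refs$name
  list(low = min(d), mid = exp(mean(log(d))), high = max(d), per_ref = d)
}

#' Predicted recovery after exposure to an absorbing material
#'
#' Closed-form recovery fraction for a compound recirculated for `time_h`
#' hours over an absorbing (PDMS-like) area with surface-to-volume ratio
#' `ratio_R_mm`:
#'
#'   recovery = max(1 - 2 R P sqrt(D t / pi), 0)
#'
#' with P = 10^log_p standing in for the PDMS-water partition coefficient and
#' D the diffusivity inside the material. The loss term is the exact
#' constant-concentration semi-infinite-slab uptake; neglecting liquid
#' depletion means loss is linear in R and exactly proportional to sqrt(t)
#' until the clamp engages.
#'
#' @param log_p log10 octanol-water partition coefficient (dimensionless).
#' @param diffusivity_cm2_s Diffusivity inside the material (cm^2/s).
#' @param ratio_R_mm Absorbing-area-to-liquid-volume ratio (mm^-1), see
#'   [area_to_volume_ratio()].
#' @param time_h Exposure duration (h).
#' @return Recovery fraction in `[0, 1]` (vectorised over any argument).
#' @examples
#' predicted_recovery(3.0, 1e-10, 0.04, 24)
#' @export
predicted_recovery <- function(log_p, diffusivity_cm2_s, ratio_R_mm, time_h) {
  if (any(diffusivity_cm2_s < 0) || any(ratio_R_mm < 0) || any(time_h < 0)) {
    stop("diffusivity, R and time must all be >= 0")
  }
  r_per_cm <- ratio_R_mm * 10
  p <- 10^log_p
  loss <- 2 * r_per_cm * p * sqrt(diffusivity_cm2_s * time_h * 3600 / pi)
  pmax(1 - loss, 0)
}

#' Per-compound sorption predictions with diffusivity bounds
#'
#' Runs [predicted_recovery()] for every compound of a panel at the three
#' diffusivity estimates of [estimate_diffusivity()]. Because higher
#' diffusivity means faster uptake, the low recovery bound pairs with the
#' high diffusivity estimate and vice versa.
#'
#' @param panel Panel data.frame with `id`, `log_p`, `molar_mass_Da`.
#' @param ratio_R_mm Absorbing-area-to-volume ratio (mm^-1), or a
#'   [fluidic_circuit()] whose device R is used.
#' @param time_h Exposure duration (h).
#' @param refs Reference diffusivity table (default: shipped synthetic
#'   stand-ins, see [reference_diffusivities()]).
#' @param exponent Mass-scaling exponent (default from shipped config).
#' @return data.frame of class `sorption_prediction` with columns
#'   `compound_id`, `recovery_low`, `recovery_mid`, `recovery_high`,
#'   `diffusivity_low`, `diffusivity_mid`, `diffusivity_high`,
#'   `partition_used`.
#' @export
predict_panel <- function(panel, ratio_R_mm, time_h,
                          refs = reference_diffusivities(),
                          exponent = default_mass_exponent()) {
  validate_panel(panel)
  if (inherits(ratio_R_mm, "fluidic_circuit")) {
    ratio_R_mm <- circuit_summary(ratio_R_mm)$device_R_mm
  }
  if (nrow(panel) == 0) {
    out <- data.frame(compound_id = character(0), recovery_low = numeric(0),
                      recovery_mid = numeric(0), recovery_high = numeric(0),
                      diffusivity_low = numeric(0),
                      diffusivity_mid = numeric(0),
                      diffusivity_high = numeric(0),
                      partition_used = numeric(0))
    class(out) <- c("sorption_prediction", "data.frame")
    return(out)
  }
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    d <- estimate_diffusivity(panel$molar_mass_Da[i], refs, exponent)
    data.frame(
      compound_id = panel$id[i],
      recovery_low = predicted_recovery(panel$log_p[i], d$high,
                                        ratio_R_mm, time_h),
      recovery_mid = predicted_recovery(panel$log_p[i], d$mid,
                                        ratio_R_mm, time_h),
      recovery_high = predicted_recovery(panel$log_p[i], d$low,
                                         ratio_R_mm, time_h),
      diffusivity_low = d$low, diffusivity_mid = d$mid,
      diffusivity_high = d$high,
      partition_used = 10^panel$log_p[i],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sorption_prediction", "data.frame")
  out
}
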