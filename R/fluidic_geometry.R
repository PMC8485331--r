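# Fluidic circuit geometry: shear, areas, flow conversions and the
# surface-area-to-volume ratio R that governs sorption scaling.
#
# Canonical internal units are mm / mm^2 / mm^3 / mPa.s / mm^3 per s;
# presentation units (cm^2, uL, mL/h, dyne/cm^2) are converted at the
# function boundaries.

#' Rectangular channel geometry
#'
#' @param width_mm,height_mm Channel cross-section in mm. The wide-channel
#'   shear approximation requires `width_mm > height_mm > 0`.
#' @param length_mm Optional channel length (mm).
#' @return Object of class `channel_geometry`.
#' @examples
#' channel_geometry(1.5, 0.2) # the package's reference barrier-on-chip channel
#' @export
channel_geometry <- function(width_mm, height_mm, length_mm = NA_real_) {
  if (!is.finite(width_mm) || !is.finite(height_mm) ||
      height_mm <= 0 || width_mm <= height_mm) {
    stop("channel geometry requires width_mm > height_mm > 0 ",
         "(validity condition of the wide-channel shear formula)")
  }
  structure(list(width_mm = width_mm, height_mm = height_mm,
                 length_mm = length_mm),
            class = "channel_geometry")
}

#' Tubing segment
#'
#' @param inner_diameter_mm Inner diameter (mm), > 0.
#' @param length_mm Segment length (mm), >= 0.
#' @param material Free-text material label (e.g. "PharMed BPT").
#' @return Object of class `tubing_segment`.
#' @export
tubing_segment <- function(inner_diameter_mm, length_mm, material = "") {
  if (!is.finite(inner_diameter_mm) || inner_diameter_mm <= 0) {
    stop("inner_diameter_mm must be > 0")
  }
  if (!is.finite(length_mm) || length_mm < 0) stop("length_mm must be >= 0")
  structure(list(inner_diameter_mm = inner_diameter_mm,
                 length_mm = length_mm, material = material),
            class = "tubing_segment")
}

#' Fluidic circuit description
#'
#' A perfusion circuit as seen by the sorption analysis: the wetted area of
#' the material of interest inside the device, the tubing run, any further
#' labelled wetted areas (interconnects, reservoirs), and the recirculating
#' liquid volume. The device area is an input rather than being derived from
#' channel length, mirroring how such systems are normally specified.
#'
#' @param device_area_cm2 Material-of-interest wetted area (cm^2).
#' @param tubing List of [tubing_segment()] objects (possibly empty).
#' @param other_areas_cm2 Named numeric vector of additional wetted areas
#'   (cm^2), e.g. `c(interconnects = 0.8, reservoirs = 7)`.
#' @param liquid_volume_uL Total recirculating liquid volume (uL), > 0.
#' @return Object of class `fluidic_circuit`.
#' @export
fluidic_circuit <- function(device_area_cm2, tubing = list(),
                            other_areas_cm2 = numeric(0), liquid_volume_uL) {
  if (!is.finite(device_area_cm2) || device_area_cm2 < 0) {
    stop("device_area_cm2 must be >= 0")
  }
  if (!is.finite(liquid_volume_uL) || liquid_volume_uL <= 0) {
    stop("liquid_volume_uL must be > 0")
  }
  if (length(other_areas_cm2) > 0 &&
      (is.null(names(other_areas_cm2)) || any(other_areas_cm2 < 0))) {
    stop("other_areas_cm2 must be a named vector of non-negative areas")
  }
  stopifnot(all(vapply(tubing, inherits, logical(1), "tubing_segment")))
  structure(list(device_area_cm2 = device_area_cm2, tubing = tubing,
                 other_areas_cm2 = other_areas_cm2,
                 liquid_volume_uL = liquid_volume_uL),
            class = "fluidic_circuit")
}

#' Wall shear stress in a wide rectangular channel
#'
#' Evaluates the wide-channel (w > h) approximation tau = 6 mu Q / (w h^2)
#' and reports the result in dyne/cm^2, the unit in which physiological shear
#' targets are quoted (1-10 dyne/cm^2 for endothelial/epithelial culture).
#'
#' @param viscosity_mPas Dynamic viscosity in mPa.s (medium at 37C is close
#'   to 1.0; see [viscosity_presets()] for blood-like values).
#' @param flow_mL_h Volumetric flow rate in mL/h.
#' @param geom A [channel_geometry()].
#' @return Wall shear stress in dyne/cm^2.
#' @examples
#' # 1.5 x 0.2 mm channel at 4.0 mL/h, aqueous medium: ~1.1 dyne/cm^2
#' wall_shear_stress(1.0, 4.0, channel_geometry(1.5, 0.2))
#' @export
wall_shear_stress <- function(viscosity_mPas, flow_mL_h, geom) {
  stopifnot(inherits(geom, "channel_geometry"))
  if (viscosity_mPas <= 0 || flow_mL_h < 0) {
    stop("viscosity must be positive and flow rate non-negative")
  }
  q_mm3_s <- flow_mL_h * 1000 / 3600
  # mPa.s * mm^3/s / mm^3 -> mPa = 1e-3 Pa; 1 Pa = 10 dyne/cm^2
  tau_mPa <- 6 * viscosity_mPas * q_mm3_s /
    (geom$width_mm * geom$height_mm^2)
  tau_mPa * 1e-3 * 10
}

#' Named viscosity presets (mPa.s)
#'
#' `aqueous` is the default used with the printed flow/shear operating point;
#' `in_vivo_low`/`in_vivo_high` bracket blood-like viscosities.
#' @return Named numeric vector.
#' @export
viscosity_presets <- function() {
  c(aqueous = 1.0, in_vivo_low = 3.0, in_vivo_high = 4.0)
}

#' Wetted inner area of a tubing run
#'
#' Sum of pi * d * L over segments, in cm^2. Additive over concatenation.
#'
#' @param segments A list of [tubing_segment()] objects.
#' @return Total wetted area in cm^2.
#' @examples
#' # 79 cm of 0.285 mm (average) ID tubing: ~7.1 cm^2
#' tubing_wetted_area(list(tubing_segment(0.285, 790)))
#' @export
tubing_wetted_area <- function(segments) {
  stopifnot(all(vapply(segments, inherits, logical(1), "tubing_segment")))
  if (length(segments) == 0) return(0)
  a_mm2 <- sum(vapply(segments, function(s) {
    pi * s$inner_diameter_mm * s$length_mm
  }, numeric(1)))
  a_mm2 / 100
}

#' Flow rate from linear pump speed
#'
#' Ideal plug-flow conversion Q = v * pi d^2 / 4 for peristaltic pumps whose
#' speed is set as a linear velocity. Real peristaltic throughput depends on
#' tubing compliance and must be calibrated; this function returns the ideal
#' geometric value (see the methods vignette for the documented discrepancy
#' with calibrated rates in softer tubing).
#'
#' @param speed_mm_s Linear speed in mm/s.
#' @param inner_diameter_mm Tubing inner diameter in mm.
#' @return Volumetric flow rate in mL/h.
#' @examples
#' flow_rate_from_linear_speed(17.5, 0.285) # ~4.0 mL/h
#' @export
flow_rate_from_linear_speed <- function(speed_mm_s, inner_diameter_mm) {
  if (speed_mm_s < 0 || inner_diameter_mm <= 0) {
    stop("speed must be >= 0 and diameter > 0")
  }
  q_mm3_s <- speed_mm_s * pi * inner_diameter_mm^2 / 4
  q_mm3_s * 3600 / 1000
}

#' Surface-area-to-volume ratio R
#'
#' R = wetted area / liquid volume in mm^-1, the key scaling variable for
#' sorption in perfused systems: studies with R ~ 10/mm sit in a different
#' sorption regime than chip-scale recirculating circuits with R ~ 0.04/mm.
#'
#' @param area_cm2 Wetted area of the material of interest (cm^2).
#' @param volume_uL Total liquid volume (uL).
#' @return R in mm^-1.
#' @examples
#' area_to_volume_ratio(1, 2500)  # 0.04/mm, recirculating chip circuit
#' area_to_volume_ratio(0.3, 30)  # 1.0/mm, small-volume immersion study
#' @export
area_to_volume_ratio <- function(area_cm2, volume_uL) {
  if (!is.finite(volume_uL) || volume_uL <= 0) stop("volume_uL must be > 0")
  if (area_cm2 < 0) stop("area_cm2 must be >= 0")
  (area_cm2 * 100) / volume_uL
}

#' Summarise a fluidic circuit
#'
#' @param circuit A [fluidic_circuit()].
#' @return List with `tubing_area_cm2`, `total_area_cm2` (device + tubing +
#'   other), `device_R_mm` (device area over volume, the sorption-model R),
#'   and `total_R_mm`.
#' @export
circuit_summary <- function(circuit) {
  stopifnot(inherits(circuit, "fluidic_circuit"))
  tub <- tubing_wetted_area(circuit$tubing)
  total <- circuit$device_area_cm2 + tub + sum(circuit$other_areas_cm2)
  list(
    tubing_area_cm2 = tub,
    total_area_cm2 = total,
    device_R_mm = area_to_volume_ratio(circuit$device_area_cm2,
                                       circuit$liquid_volume_uL),
    total_R_mm = area_to_volume_ratio(total, circuit$liquid_volume_uL)
  )
}

#' Read a fluidic circuit from JSON
#'
#' Format:
#' `{device_area_cm2, liquid_volume_uL, tubing:[{d_mm,len_mm,material}],
#' other_areas:{label:cm2}}`.
#'
#' @param path Path to a JSON file.
#' @return A [fluidic_circuit()].
#' @export
read_circuit_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  tubing <- lapply(j$tubing, function(s) {
    tubing_segment(s$d_mm, s$len_mm,
                   material = if (is.null(s$material)) "" else s$material)
  })
  other <- unlist(j$other_areas)
  if (is.null(other)) other <- numeric(0)
  fluidic_circuit(
    device_area_cm2 = j$device_area_cm2,
    tubing = tubing,
    other_areas_cm2 = other,
    liquid_volume_uL = j$liquid_volume_uL
  )
}
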