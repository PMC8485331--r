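# Recovery statistics: replicate means with t confidence intervals, MOVER-R
# propagation into ratio-based recoveries, LOQ censoring, and surface-area
# normalization.

#' One condition's replicate measurements for one compound
#'
#' @param compound_id Compound code (e.g. "Am").
#' @param condition One of "frozen", "vessel", "tubing_only", "device" (free
#'   text is accepted for additional conditions).
#' @param values Non-negative replicate concentrations (mol/L or normalized
#'   C', recorded in `units`).
#' @param loq Assay limit of quantification in the same units (NA if none).
#' @param units Unit label, default "mol_per_L".
#' @param material,medium Optional tags (e.g. "PDMS", "CCM").
#' @return Object of class `measurement_set`.
#' @export
measurement_set <- function(compound_id, condition, values, loq = NA_real_,
                            units = "mol_per_L", material = NA_character_,
                            medium = NA_character_) {
  if (length(values) < 1) stop("at least one replicate value is required")
  if (any(values < 0)) stop("replicate values must be non-negative")
  structure(
    list(compound_id = compound_id, condition = condition,
         values = as.numeric(values), n = length(values), loq = loq,
         units = units, material = material, medium = medium,
         censored = NA),
    class = "measurement_set"
  )
}

#' Replicate mean with Student-t confidence interval
#'
#' mean +/- t_{(1+level)/2, n-1} * sd / sqrt(n). A single value yields a
#' degenerate zero-width interval flagged `degenerate = TRUE`.
#'
#' @param values Numeric replicate values (or a [measurement_set()]).
#' @param level Confidence level, default 0.95.
#' @return Object of class `interval_estimate`: `mean`, `lower`, `upper`,
#'   `level`, `n`, `degenerate`.
#' @examples
#' mean_ci(c(1, 2, 3, 4)) # (0.446, 4.554)
#' @export
mean_ci <- function(values, level = 0.95) {
  if (inherits(values, "measurement_set")) values <- values$values
  if (length(values) == 0) stop("cannot compute a mean of zero values")
  m <- mean(values)
  if (length(values) == 1) {
    return(structure(list(mean = m, lower = m, upper = m, level = level,
                          n = 1L, degenerate = TRUE),
                     class = "interval_estimate"))
  }
  n <- length(values)
  half <- stats::qt((1 + level) / 2, df = n - 1) * stats::sd(values) / sqrt(n)
  structure(list(mean = m, lower = m - half, upper = m + half, level = level,
                 n = as.integer(n), degenerate = FALSE),
            class = "interval_estimate")
}

#' MOVER-R confidence interval for a ratio of two means
#'
#' Propagates the component 95% (or other level) confidence intervals into
#' the ratio of means by the closed-form method of variance estimates
#' recovery for ratios. With numerator (m1; l1, u1) and denominator
#' (m2; l2, u2):
#'
#'   L = \[m1 m2 - sqrt((m1 m2)^2 - l1 u2 (2 m1 - l1)(2 m2 - u2))\] /
#'       \[u2 (2 m2 - u2)\]
#'
#' and U analogously with u1 and l2. When the denominator interval is a point
#' (exact denominator), this reduces to simple interval division.
#'
#' @param numerator,denominator [interval_estimate()] objects at the same
#'   confidence level; the denominator interval must exclude 0.
#' @param compound_id Optional compound code carried on the result.
#' @return Object of class `recovery_estimate`: `compound_id`, `ratio`,
#'   `lower`, `upper`, `level`, `censored` ("none" here).
#' @examples
#' num <- structure(list(mean = 10, lower = 8, upper = 12, level = 0.95,
#'                       n = 4L, degenerate = FALSE), class = "interval_estimate")
#' den <- structure(list(mean = 5, lower = 4, upper = 6, level = 0.95,
#'                       n = 4L, degenerate = FALSE), class = "interval_estimate")
#' mover_r_ratio(num, den) # ratio 2, CI (1.5, 2.667)
#' @export
mover_r_ratio <- function(numerator, denominator, compound_id = NA_character_) {
  stopifnot(inherits(numerator, "interval_estimate"),
            inherits(denominator, "interval_estimate"))
  if (!isTRUE(all.equal(numerator$level, denominator$level))) {
    stop("numerator and denominator intervals are at different levels")
  }
  m1 <- numerator$mean; l1 <- numerator$lower; u1 <- numerator$upper
  m2 <- denominator$mean; l2 <- denominator$lower; u2 <- denominator$upper
  if (m2 <= 0) stop("denominator mean must be > 0")
  if (l2 <= 0) {
    stop("denominator interval contains 0: ratio CI undefined in this regime")
  }
  if (2 * m2 - u2 <= 0) {
    stop("denominator interval too wide relative to its mean (2*m - upper <= 0)")
  }
  disc_l <- (m1 * m2)^2 - l1 * u2 * (2 * m1 - l1) * (2 * m2 - u2)
  disc_u <- (m1 * m2)^2 - u1 * l2 * (2 * m1 - u1) * (2 * m2 - l2)
  # zero-width intervals make the discriminant an exact zero that floating
  # point can undershoot; clamp only that numerical fuzz
  tol <- 1e-9 * (m1 * m2)^2
  if (disc_l > -tol) disc_l <- max(disc_l, 0)
  if (disc_u > -tol) disc_u <- max(disc_u, 0)
  if (disc_l < 0 || disc_u < 0) {
    stop("MOVER-R discriminant negative: component intervals are inconsistent")
  }
  lower <- (m1 * m2 - sqrt(disc_l)) / (u2 * (2 * m2 - u2))
  upper <- (m1 * m2 + sqrt(disc_u)) / (l2 * (2 * m2 - l2))
  structure(list(compound_id = compound_id, ratio = m1 / m2, lower = lower,
                 upper = upper, level = numerator$level, censored = "none",
                 normalized_area_cm2 = NA_real_),
            class = "recovery_estimate")
}

#' Flag a measurement set that falls below the assay LOQ
#'
#' The comparison is strict (`< loq`): a mean exactly at the LOQ remains
#' quantifiable. The default compares the replicate mean; `rule =
#' "any_replicate"` instead censors when any single replicate is below the
#' LOQ (a configuration switch, since either convention is defensible).
#' Censored sets are excluded from downstream device-ratio analysis and
#' reported with uncapped lower error bars.
#'
#' @param m A [measurement_set()] with `loq` present.
#' @param rule "mean" (default) or "any_replicate".
#' @return The measurement set with `censored` set to `"below_loq"` or
#'   `"none"`.
#' @export
censor_by_loq <- function(m, rule = c("mean", "any_replicate")) {
  stopifnot(inherits(m, "measurement_set"))
  rule <- match.arg(rule)
  if (is.na(m$loq)) stop("measurement set has no LOQ recorded")
  below <- switch(rule,
                  mean = mean(m$values) < m$loq,
                  any_replicate = any(m$values < m$loq))
  m$censored <- if (below) "below_loq" else "none"
  m
}

#' Normalize a recovery to a reference surface area
#'
#' Applies the first-order surface-loss model: if a fraction survives contact
#' with area A, the survival over area A' is recovery^(A'/A). The CI bounds
#' are transformed through the same monotone power map. Exponent
#' multiplicativity makes normalization compose: 10 -> 5 -> 1 cm^2 equals
#' 10 -> 1 cm^2 directly.
#'
#' @param r A [recovery_estimate()] with ratio in (0, 1].
#' @param measured_area_cm2 Area at which the recovery was measured (> 0).
#' @param target_area_cm2 Area to normalize to (> 0).
#' @return The recovery estimate rescaled, with `normalized_area_cm2` set.
#' @examples
#' # 0.81 measured at 10 cm^2 becomes 0.9 at 5 cm^2
#' @export
normalize_recovery_area <- function(r, measured_area_cm2, target_area_cm2) {
  stopifnot(inherits(r, "recovery_estimate"))
  if (measured_area_cm2 <= 0 || target_area_cm2 <= 0) {
    stop("areas must be > 0")
  }
  if (r$ratio == 0 && target_area_cm2 < measured_area_cm2) {
    stop("cannot extrapolate a zero recovery to a smaller area")
  }
  if (r$ratio < 0 || r$ratio > 1) {
    stop("area normalization requires recovery in (0, 1]")
  }
  k <- target_area_cm2 / measured_area_cm2
  r$ratio <- r$ratio^k
  r$lower <- r$lower^k
  r$upper <- r$upper^k
  r$normalized_area_cm2 <- target_area_cm2
  r
}

#' Chain of recovery ratios for one compound
#'
#' Decomposes the endpoint measurement into the three multiplicative stages
#' the experimental design isolates: device contribution (device /
#' tubing-only), tubing contribution (tubing-only / vessel) and inherent
#' degradation (vessel / frozen), each with a MOVER-R confidence interval.
#' LOQ censoring propagates: a censored denominator blocks the dependent
#' ratio, and a censored numerator is reported with an uncapped lower bound
#' (`lower = 0`, `censored = "below_loq"`).
#'
#' @param device,tubing_only,vessel,frozen [measurement_set()] objects for
#'   the same compound and units. `device` may be NULL for tubing-only
#'   circuits.
#' @param level Confidence level, default 0.95.
#' @param censor_rule Passed to [censor_by_loq()] where an LOQ is present.
#' @return data.frame with one row per ratio: `compound_id`, `ratio_name`
#'   ("device_over_tubing", "tubing_over_vessel", "vessel_over_frozen"),
#'   `ratio`, `lower`, `upper`, `censored`.
#' @export
recovery_chain <- function(device, tubing_only, vessel, frozen, level = 0.95,
                           censor_rule = "mean") {
  sets <- Filter(Negate(is.null),
                 list(device = device, tubing_only = tubing_only,
                      vessel = vessel, frozen = frozen))
  ids <- unique(vapply(sets, `[[`, character(1), "compound_id"))
  if (length(ids) != 1) stop("all measurement sets must be for one compound")
  units <- unique(vapply(sets, `[[`, character(1), "units"))
  if (length(units) != 1) stop("unit mismatch between measurement sets")

  flag <- function(m) {
    if (is.null(m) || is.na(m$loq)) return("none")
    censor_by_loq(m, rule = censor_rule)$censored
  }
  cens <- lapply(sets, flag)

  one_ratio <- function(num, den, name) {
    if (is.null(num) || is.null(den)) return(NULL)
    num_c <- cens[[num]]; den_c <- cens[[den]]
    if (identical(den_c, "below_loq")) {
      # denominator unquantifiable: the dependent ratio is blocked
      return(data.frame(compound_id = ids, ratio_name = name, ratio = NA_real_,
                        lower = NA_real_, upper = NA_real_,
                        censored = "blocked_denominator",
                        stringsAsFactors = FALSE))
    }
    est <- mover_r_ratio(mean_ci(sets[[num]], level),
                         mean_ci(sets[[den]], level), compound_id = ids)
    if (identical(num_c, "below_loq")) {
      est$censored <- "below_loq"
      est$lower <- 0 # uncapped: the true value lies anywhere below the LOQ
    }
    data.frame(compound_id = ids, ratio_name = name, ratio = est$ratio,
               lower = est$lower, upper = est$upper, censored = est$censored,
               stringsAsFactors = FALSE)
  }

  out <- rbind(
    one_ratio("device", "tubing_only", "device_over_tubing"),
    one_ratio("tubing_only", "vessel", "tubing_over_vessel"),
    one_ratio("vessel", "frozen", "vessel_over_frozen")
  )
  rownames(out) <- NULL
  out
}

#' Analyze a simulated (or measured) experiment end to end
#'
#' Runs the full estimator chain on a long-format measurement table as
#' produced by [simulate_experiment()]: per-compound LOQ censoring, the
#' three-stage recovery chain with MOVER-R intervals, area normalization of
#' the tubing recoveries to `target_area_cm2`, and the fixed-intercept
#' log-log TPSA trend fit over the quantifiable compounds.
#'
#' @param measurements Long data.frame with columns `compound_id`,
#'   `condition`, `replicate`, `value`, `loq`, `tpsa_nm2` (conditions
#'   "frozen", "vessel", "tubing_only", "device"; `device` rows optional).
#' @param tubing_area_cm2 Wetted tubing area at which the measurements were
#'   taken; defaults to the generator config attached to `measurements`.
#' @param target_area_cm2 Area the tubing trend is normalized to (default 1,
#'   the device-equivalent basis).
#' @param level Confidence level (default 0.95).
#' @param censor_rule Passed to [censor_by_loq()].
#' @return List with `recoveries` (per compound x ratio data.frame, tubing
#'   rows additionally carrying `ratio_norm`/`lower_norm`/`upper_norm` at the
#'   target area), `trend` (a [fixed_intercept_loglog_fit()] over normalized
#'   tubing recoveries of quantifiable compounds), and `censored_ids`.
#' @export
analyze_experiment <- function(measurements, tubing_area_cm2 = NULL,
                               target_area_cm2 = 1, level = 0.95,
                               censor_rule = "mean") {
  cfg <- attr(measurements, "config")
  if (is.null(tubing_area_cm2)) {
    if (is.null(cfg)) {
      stop("tubing_area_cm2 must be given when measurements carry no config")
    }
    tubing_area_cm2 <- cfg$material_areas[["tubing"]]
  }

  split_sets <- split(measurements, measurements$compound_id)
  chains <- list()
  trend_rows <- list()
  censored_ids <- character(0)

  for (id in names(split_sets)) {
    d <- split_sets[[id]]
    ms <- function(cond) {
      rows <- d[d$condition == cond, , drop = FALSE]
      if (nrow(rows) == 0) return(NULL)
      measurement_set(id, cond, rows$value, loq = rows$loq[1])
    }
    chain <- recovery_chain(ms("device"), ms("tubing_only"), ms("vessel"),
                            ms("frozen"), level = level,
                            censor_rule = censor_rule)
    tub <- chain[chain$ratio_name == "tubing_over_vessel", ]
    quantifiable <- nrow(tub) == 1 && identical(tub$censored, "none")
    if (!quantifiable) censored_ids <- c(censored_ids, id)

    chain$ratio_norm <- NA_real_
    chain$lower_norm <- NA_real_
    chain$upper_norm <- NA_real_
    if (quantifiable && tub$ratio > 0) {
      # same power map as normalize_recovery_area(), applied directly so that
      # noisy recoveries marginally above 1 are retained rather than truncated
      # (truncation would bias the trend slope toward sorption)
      k <- target_area_cm2 / tubing_area_cm2
      i <- chain$ratio_name == "tubing_over_vessel"
      chain$ratio_norm[i] <- tub$ratio^k
      chain$lower_norm[i] <- tub$lower^k
      chain$upper_norm[i] <- tub$upper^k
      trend_rows[[id]] <- data.frame(compound_id = id,
                                     tpsa_nm2 = d$tpsa_nm2[1],
                                     recovery = tub$ratio^k,
                                     stringsAsFactors = FALSE)
    }
    chains[[id]] <- chain
  }

  recoveries <- do.call(rbind, chains)
  rownames(recoveries) <- NULL
  trend_df <- do.call(rbind, trend_rows)

  trend <- NULL
  if (!is.null(trend_df) && nrow(trend_df) >= 3) {
    trend <- fixed_intercept_loglog_fit(trend_df$tpsa_nm2, trend_df$recovery,
                                        material = "tubing",
                                        norm_area_cm2 = target_area_cm2)
  }

  list(recoveries = recoveries, trend = trend, censored_ids = censored_ids)
}
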