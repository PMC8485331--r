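# Compound panel: identities, dosing concentrations and molecular descriptors.

#' Controlled vocabulary of extended molecular descriptors
#'
#' Names of the descriptor set used by the PLS variable-importance analysis:
#' 21 computed physicochemical parameters plus the experimental concentration
#' term `log_c_over_m` (log10 of molar concentration, C/M). Descriptor tables
#' passed to [build_descriptor_matrix()] must draw their column names from
#' this vocabulary; unknown names are rejected to prevent silent PLS
#' misconfiguration.
#'
#' @return Character vector of 22 descriptor names.
#' @export
descriptor_vocabulary <- function() {
  c(
    "molar_mass", "asymmetric_atom_count", "rotatable_bond_count",
    "ring_count", "aromatic_ring_count", "hetero_ring_count",
    "fraction_sp3", "hbond_donor_count", "hbond_acceptor_count",
    "log_tpsa", "polarizability", "charge_ph74", "log_p", "log_d74",
    "log_s", "log_s74", "vdw_volume", "vdw_surface_area",
    "solvent_accessible_surface_area", "min_projection_area",
    "max_projection_area", "log_c_over_m"
  )
}

#' Built-in study compound panel
#'
#' The 18-compound panel used throughout the package: 15 neuropsychopharmaca
#' dosed at 5/6th of their upper therapeutic plasma range, plus 3 fluorophores.
#' Values are read from a checked-in fixture (`inst/extdata/compound_panel.csv`)
#' and reported exactly as shipped: mass concentration in g/L, molar mass in
#' Da, octanol-water log P, topological polar surface area (TPSA) in nm^2, and
#' H-bond donor count.
#'
#' TPSA is kept in nm^2 throughout the package (the trend-fit intercept
#' convention is 100% recovery at 1 nm^2); use [nm2_to_A2()]/[A2_to_nm2()]
#' for explicit conversion.
#'
#' @return A data.frame with columns `id`, `name`, `class`, `conc_g_per_L`,
#'   `molar_mass_Da`, `log_p`, `tpsa_nm2`, `hbd`.
#' @examples
#' panel <- builtin_panel()
#' panel[panel$id == "Am", ]
#' @export
builtin_panel <- function() {
  path <- system.file("extdata", "compound_panel.csv", package = "chipsorb",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  data.frame(
    id = raw$id,
    name = raw$name,
    class = raw$class,
    conc_g_per_L = raw$conc_g_per_L,
    molar_mass_Da = raw$molar_mass_Da,
    log_p = raw$logP,
    tpsa_nm2 = raw$TPSA_nm2,
    hbd = as.integer(raw$HBd),
    stringsAsFactors = FALSE
  )
}

#' Read a compound panel from CSV
#'
#' Expects the header
#' `id,name,class,conc_g_per_L,molar_mass_Da,logP,TPSA_nm2,HBd` optionally
#' followed by extended descriptor columns named from
#' [descriptor_vocabulary()].
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A data.frame as in [builtin_panel()]; extended descriptor columns,
#'   if present, are carried through unchanged.
#' @export
read_panel_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("id", "name", "class", "conc_g_per_L", "molar_mass_Da",
                "logP", "TPSA_nm2", "HBd")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("panel CSV is missing required columns: ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(raw), required)
  unknown <- setdiff(extra, descriptor_vocabulary())
  if (length(unknown) > 0) {
    stop("unknown descriptor columns in panel CSV: ",
         paste(unknown, collapse = ", "),
         " (see descriptor_vocabulary())")
  }
  out <- data.frame(
    id = raw$id, name = raw$name, class = raw$class,
    conc_g_per_L = raw$conc_g_per_L, molar_mass_Da = raw$molar_mass_Da,
    log_p = raw$logP, tpsa_nm2 = raw$TPSA_nm2, hbd = as.integer(raw$HBd),
    stringsAsFactors = FALSE
  )
  validate_panel(out)
  cbind(out, raw[extra])
}

validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel))
  if (any(!is.finite(panel$molar_mass_Da)) || any(panel$molar_mass_Da <= 0)) {
    stop("molar_mass_Da must be positive for all compounds")
  }
  if (any(panel$tpsa_nm2 < 0, na.rm = TRUE)) stop("tpsa_nm2 must be >= 0")
  present <- !is.na(panel$conc_g_per_L)
  if (any(panel$conc_g_per_L[present] <= 0)) {
    stop("conc_g_per_L must be positive where present")
  }
  invisible(panel)
}

#' Molar dosing concentration
#'
#' Converts the panel's mass concentrations (g/L) to molarity (mol/L), the
#' unit in which assay limits of quantification are expressed.
#'
#' @param panel A panel data.frame (or subset of rows) with `conc_g_per_L`
#'   and `molar_mass_Da` columns.
#' @return Named numeric vector of molar concentrations (mol/L), keyed by
#'   compound id.
#' @examples
#' molar_concentration(builtin_panel())[["Am"]] # ~6.14e-7 mol/L
#' @export
molar_concentration <- function(panel) {
  if (!is.data.frame(panel) ||
      !all(c("conc_g_per_L", "molar_mass_Da") %in% names(panel))) {
    stop("panel must contain conc_g_per_L and molar_mass_Da columns")
  }
  if (any(is.na(panel$conc_g_per_L)) || any(is.na(panel$molar_mass_Da))) {
    bad <- panel$id[is.na(panel$conc_g_per_L) | is.na(panel$molar_mass_Da)]
    stop("missing conc_g_per_L or molar_mass_Da for: ",
         paste(bad, collapse = ", "))
  }
  stats::setNames(panel$conc_g_per_L / panel$molar_mass_Da, panel$id)
}

#' @rdname tpsa_units
#' @export
nm2_to_A2 <- function(x) x * 100

#' TPSA unit conversion
#'
#' Explicit converters between nm^2 (the package-internal TPSA unit) and
#' Angstrom^2 (the unit most descriptor software prints). Conversions are
#' never applied implicitly.
#'
#' @param x Numeric area value(s).
#' @return Converted numeric value(s).
#' @name tpsa_units
#' @export
A2_to_nm2 <- function(x) x / 100

#' Assemble a descriptor matrix for multivariate analysis
#'
#' Builds the numeric compound-by-descriptor matrix consumed by [pls_vip()].
#' Two transforms are applied at this boundary: TPSA enters as `log_tpsa`
#' (log10 of the nm^2 value) and the experimental concentration enters as
#' `log_c_over_m` (log10 of molar concentration). Missing `log_s` entries
#' (a known failure mode of descriptor software for resonance-delocalized
#' dyes) are imputed with the average of the compounds for which it could be
#' computed. Columns may finally be autoscaled to mean 0 / unit variance, the
#' standard PLS preprocessing.
#'
#' @param panel Panel data.frame (see [builtin_panel()]); supplies `tpsa_nm2`,
#'   `conc_g_per_L` and `molar_mass_Da`.
#' @param descriptors A data.frame with an `id` column matching the panel plus
#'   descriptor columns named from [descriptor_vocabulary()] (excluding the
#'   two derived columns, which are computed here). `log_s` may contain NA.
#' @param autoscale Autoscale columns (default TRUE).
#' @param impute_log_s Replace missing `log_s` (and `log_s74`) values by the
#'   across-compound average (default TRUE). With FALSE, any missing value is
#'   an error naming the descriptor and compound.
#' @return An object of class `descriptor_matrix`: list with `values` (numeric
#'   matrix, rownames = compound ids), `compounds`, `names`, and
#'   `transforms_applied`.
#' @export
build_descriptor_matrix <- function(panel, descriptors, autoscale = TRUE,
                                    impute_log_s = TRUE) {
  validate_panel(panel)
  if (!"id" %in% names(descriptors)) stop("descriptors must have an id column")
  if (!all(panel$id %in% descriptors$id)) {
    stop("descriptors missing for compounds: ",
         paste(setdiff(panel$id, descriptors$id), collapse = ", "))
  }
  descriptors <- descriptors[match(panel$id, descriptors$id), , drop = FALSE]

  vocab <- descriptor_vocabulary()
  cols <- setdiff(names(descriptors), "id")
  unknown <- setdiff(cols, vocab)
  if (length(unknown) > 0) {
    stop("unknown descriptor names: ", paste(unknown, collapse = ", "),
         " (see descriptor_vocabulary())")
  }

  m <- as.matrix(descriptors[, cols, drop = FALSE])
  rownames(m) <- panel$id
  transforms <- character(0)

  # derived columns from the panel itself
  if (!"log_tpsa" %in% cols) {
    if (any(panel$tpsa_nm2 <= 0)) stop("tpsa_nm2 must be > 0 to take log")
    m <- cbind(m, log_tpsa = log10(panel$tpsa_nm2))
    transforms <- c(transforms, "log_tpsa = log10(tpsa_nm2)")
  }
  if (!"log_c_over_m" %in% colnames(m)) {
    m <- cbind(m, log_c_over_m = log10(molar_concentration(panel)))
    transforms <- c(transforms,
                    "log_c_over_m = log10(conc_g_per_L / molar_mass_Da)")
  }

  # imputation: log S style columns may be incomputable for some compounds
  imputable <- intersect(c("log_s", "log_s74"), colnames(m))
  for (col in colnames(m)) {
    nas <- is.na(m[, col])
    if (!any(nas)) next
    if (impute_log_s && col %in% imputable && !all(nas)) {
      m[nas, col] <- mean(m[!nas, col])
      transforms <- c(transforms, sprintf(
        "%s: imputed %d missing value(s) with across-compound mean",
        col, sum(nas)))
    } else {
      stop(sprintf("missing descriptor '%s' for compound(s) %s with no imputation rule",
                   col, paste(rownames(m)[nas], collapse = ", ")))
    }
  }

  if (autoscale) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      stop("cannot autoscale constant descriptor column(s): ",
           paste(colnames(m)[sds == 0], collapse = ", "))
    }
    m <- scale(m)
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
    transforms <- c(transforms, "autoscaled (mean 0, unit variance)")
  }

  structure(
    list(values = m, compounds = rownames(m), names = colnames(m),
         autoscaled = autoscale, transforms_applied = transforms),
    class = "descriptor_matrix"
  )
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor_matrix> %d compounds x %d descriptors%s\n",
              nrow(x$values), ncol(x$values),
              if (x$autoscaled) " (autoscaled)" else ""))
  for (t in x$transforms_applied) cat(" -", t, "\n")
  invisible(x)
}
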