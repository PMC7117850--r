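#' Calibration constants for density and modulus mapping
#'
#' Single source of truth for the scanner calibration chain used by the
#' micro-FE material mapping: an affine grayscale-to-Hounsfield map
#' (HU = 18.278 g - 1000), an affine HU-to-density map
#' (rho = 3.821e-3 HU - 0.062 g/cm^3), and a quadratic density-to-modulus
#' power law E = E_max (rho / rho_max)^2 with E_max = 28.6 GPa at
#' rho_max = 1.762 g/cm^3. Also carries the global segmentation threshold
#' (grayscale 65, equivalent CaHA density 0.413 g/cm^3) and Poisson's ratio
#' 0.3. Any field can be overridden, or loaded from a YAML/JSON config via
#' \code{\link{load_calibration}}.
#'
#' Note that the threshold's stated CaHA-equivalent density (0.413 g/cm^3)
#' comes from the hydroxyapatite phantom calibration, which is a different
#' map from the HU chain used for FE moduli; the two calibrations coexist
#' and are deliberately kept separate (see \code{\link{fit_phantom_map}}).
#'
#' @param ... named overrides of the defaults listed above.
#' @return a \code{calibration_constants} list.
#' @export
calibration_constants <- function(...) {
  consts <- list(
    hu_slope = 18.278,          # HU per grayscale level
    hu_intercept = -1000,       # HU
    rho_slope = 3.821e-3,       # g/cm^3 per HU
    rho_intercept = -0.062,     # g/cm^3
    E_max = 28.6,               # GPa
    rho_max = 1.762,            # g/cm^3
    poisson_nu = 0.3,
    threshold_grayscale = 65,
    threshold_density_equiv = 0.413  # g/cm^3 CaHA (phantom calibration)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(consts))
  if (length(bad)) stop("unknown calibration field(s): ", paste(bad, collapse = ", "))
  consts[names(over)] <- over
  with(consts, {
    stopifnot(E_max > 0, rho_max > 0, poisson_nu > 0, poisson_nu < 0.5,
              threshold_grayscale >= 0, threshold_grayscale <= 255)
  })
  structure(consts, class = "calibration_constants")
}

#' Load calibration constants from a YAML or JSON config file
#'
#' Fields present in the file override the defaults; absent fields keep them.
#'
#' @param path YAML (.yml/.yaml) or JSON file with a flat mapping of fields.
#' @export
load_calibration <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(calibration_constants, as.list(vals))
}

#' Grayscale to Hounsfield units
#'
#' @param g grayscale values (0-255 scale; vectorised).
#' @param consts a \code{\link{calibration_constants}}.
#' @return HU values.
#' @export
grayscale_to_hu <- function(g, consts = calibration_constants()) {
  stopifnot(all(is.finite(g)))
  consts$hu_slope * g + consts$hu_intercept
}

#' Hounsfield units to apparent density
#'
#' No clamping is applied here: the affine map can return negative densities
#' at low HU, and it is the mesh builder's job to clamp before the modulus
#' power law.
#'
#' @param hu Hounsfield units (vectorised).
#' @inheritParams grayscale_to_hu
#' @return density in g/cm^3.
#' @export
hu_to_density <- function(hu, consts = calibration_constants()) {
  stopifnot(all(is.finite(hu)))
  consts$rho_slope * hu + consts$rho_intercept
}

#' Density to elastic modulus (quadratic power law)
#'
#' E = E_max * (rho / rho_max)^2. Negative densities are an error: callers
#' must clamp (see \code{\link{build_mesh}}) before mapping to modulus.
#'
#' @param rho density in g/cm^3 (vectorised), must be >= 0.
#' @inheritParams grayscale_to_hu
#' @return Young's modulus in GPa.
#' @export
density_to_modulus <- function(rho, consts = calibration_constants()) {
  if (any(!is.finite(rho)) || any(rho < 0))
    stop("density_to_modulus: rho must be finite and non-negative; clamp first")
  consts$E_max * (rho / consts$rho_max)^2
}

#' Fit the hydroxyapatite phantom density calibration
#'
#' Two-point linear map taking the mean grayscale of the low- and
#' high-density phantom inserts to their nominal CaHA densities. This is the
#' calibration used for BMD/TMD reporting; it is distinct from the HU-based
#' chain used for FE moduli and the two are not interchangeable.
#'
#' @param mean_gs_low,mean_gs_high mean grayscale over each insert.
#' @param densities nominal insert densities in g/cm^3.
#' @return a \code{phantom_density_map}: call it, or pass to
#'   \code{\link{mean_density}}.
#' @export
fit_phantom_map <- function(mean_gs_low, mean_gs_high,
                            densities = c(0.25, 0.75)) {
  if (!(mean_gs_high > mean_gs_low))
    stop("phantom insert grayscales must satisfy mean_gs_high > mean_gs_low")
  slope <- (densities[2] - densities[1]) / (mean_gs_high - mean_gs_low)
  intercept <- densities[1] - slope * mean_gs_low
  f <- function(g) slope * g + intercept
  structure(f, slope = slope, intercept = intercept,
            nodes_grayscale = c(mean_gs_low, mean_gs_high),
            nodes_density = densities,
            class = c("phantom_density_map", "function"))
}

#' Global threshold segmentation
#'
#' Binary bone mask: grayscale >= threshold (inclusive by convention; the
#' convention is fixed so tests are bit-exact).
#'
#' @param vol an \code{\link{image_volume}} or a numeric array.
#' @param t threshold on the 0-255 grayscale scale; defaults to the global
#'   threshold of 65.
#' @return logical array of the input's shape.
#' @export
segment_threshold <- function(vol, t = calibration_constants()$threshold_grayscale) {
  stopifnot(t >= 0, t <= 255)
  data <- if (inherits(vol, "image_volume")) vol$data else vol
  array(data >= t, dim(data))
}

#' Displacement calibration table for loading by age
#'
#' Peak actuator displacements that produce the target tensile strain levels
#' (450, 850, 1250 microstrain) on the medio-proximal tibial surface at the
#' strain-gauge calibration ages 4, 8 and 12 weeks. The source figures print
#' no numeric values, so the defaults are configurable placeholders with the
#' right order of magnitude; supply measured values for real use.
#'
#' @param ages calibration ages in weeks (strictly increasing).
#' @param levels target strain levels in microstrain.
#' @param displacements matrix (ages x levels) of displacements in mm.
#' @export
displacement_table <- function(ages = c(4, 8, 12),
                               levels = c(450, 850, 1250),
                               displacements = NULL) {
  if (is.null(displacements)) {
    # placeholder: displacement grows with age (stiffer bone needs more
    # travel at fixed strain gauge site) and with target strain
    displacements <- outer(c(0.10, 0.14, 0.18), levels / 850)
  }
  displacements <- as.matrix(displacements)
  stopifnot(all(diff(ages) > 0), all(displacements > 0),
            nrow(displacements) == length(ages),
            ncol(displacements) == length(levels))
  dimnames(displacements) <- list(age = ages, level = levels)
  structure(list(ages = ages, levels = levels, displacements = displacements),
            class = "displacement_table")
}

#' Interpolate the loading displacement for an age between calibration ages
#'
#' Piecewise-linear in age, exact at the calibration ages; no extrapolation
#' outside the calibrated range.
#'
#' @param table a \code{\link{displacement_table}}.
#' @param age animal age in weeks, within the table's age range.
#' @param level target strain level in microstrain; must be a table column.
#' @return displacement in mm.
#' @export
displacement_for_age <- function(table, age, level) {
  stopifnot(inherits(table, "displacement_table"))
  if (age < min(table$ages) || age > max(table$ages))
    stop(sprintf("age %g weeks outside the calibrated range [%g, %g]; no extrapolation",
                 age, min(table$ages), max(table$ages)))
  j <- match(level, table$levels)
  if (is.na(j)) stop("strain level ", level, " not in the calibration table")
  approx(table$ages, table$displacements[, j], xout = age)$y
}
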