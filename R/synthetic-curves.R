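#' Specification of a synthetic three-point-bending curve
#'
#' Bilinear-plus-fracture force-displacement template: linear loading at
#' stiffness \code{stiffness_k} up to \code{yield_force}, a post-yield branch
#' at \code{postyield_slope} up to \code{ultimate_force}, then an abrupt
#' force drop of \code{fracture_drop_fraction} x ultimate, after which the
#' test ends. Sampling is uniform in displacement (the tests run in
#' displacement control); optional Gaussian force noise is seeded.
#'
#' @param stiffness_k elastic slope, N/mm.
#' @param yield_force knee force, N.
#' @param postyield_slope post-yield slope, N/mm (must be < stiffness_k).
#' @param ultimate_force peak force, N (> yield_force).
#' @param fracture_drop_fraction fraction of the peak force lost at the
#'   fracture sample, in (0, 1].
#' @param sampling_interval_mm displacement step between samples, mm
#'   (0.015 mm by default: 0.15 mm/s crosshead speed sampled every 0.1 s).
#' @param noise_sd force noise SD, N.
#' @param seed integer seed.
#' @export
curve_spec <- function(stiffness_k = 250, yield_force = 100,
                       postyield_slope = 25, ultimate_force = 150,
                       fracture_drop_fraction = 0.8,
                       sampling_interval_mm = 0.015,
                       noise_sd = 0, seed = 1L) {
  spec <- as.list(environment())
  with(spec, {
    stopifnot(stiffness_k > 0, yield_force > 0,
              yield_force < ultimate_force,
              postyield_slope >= 0, postyield_slope < stiffness_k,
              fracture_drop_fraction > 0, fracture_drop_fraction <= 1,
              sampling_interval_mm > 0, noise_sd >= 0)
  })
  structure(spec, class = "curve_spec")
}

#' Force-displacement curve container
#'
#' @param displacement_mm,force_N equal-length numeric vectors; displacement
#'   must be non-decreasing and at least 10 samples long.
#' @param displacement_rate_mm_s,sampling_interval_s acquisition metadata.
#' @export
force_displacement_curve <- function(displacement_mm, force_N,
                                     displacement_rate_mm_s = 0.15,
                                     sampling_interval_s = 0.1) {
  stopifnot(length(displacement_mm) == length(force_N),
            length(displacement_mm) >= 10,
            !is.unsorted(displacement_mm))
  structure(list(displacement_mm = as.numeric(displacement_mm),
                 force_N = as.numeric(force_N),
                 displacement_rate_mm_s = displacement_rate_mm_s,
                 sampling_interval_s = sampling_interval_s),
            class = "force_displacement_curve")
}

#' Generate a synthetic bending curve from a curve_spec
#'
#' @param spec a \code{\link{curve_spec}}.
#' @return a \code{\link{force_displacement_curve}}.
#' @export
generate_curve <- function(spec = curve_spec()) {
  stopifnot(inherits(spec, "curve_spec"))
  d_y <- spec$yield_force / spec$stiffness_k
  d_ult <- if (spec$postyield_slope > 0)
    d_y + (spec$ultimate_force - spec$yield_force) / spec$postyield_slope
  else d_y + 2 * d_y  # flat plateau: give it a finite ductile span
  d_end <- d_ult + 2 * spec$sampling_interval_mm
  d <- seq(0, d_end, by = spec$sampling_interval_mm)
  f <- ifelse(d <= d_y, spec$stiffness_k * d,
              pmin(spec$yield_force + spec$postyield_slope * (d - d_y),
                   spec$ultimate_force))
  post <- d > d_ult
  f[post] <- spec$ultimate_force * (1 - spec$fracture_drop_fraction)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    f <- f + rnorm(length(f), sd = spec$noise_sd)
    f[1] <- 0
  }
  force_displacement_curve(d, f)
}

#' Write / read a bending curve as a two-column CSV
#'
#' Columns \code{displacement_mm}, \code{force_N}, with header.
#'
#' @param curve a \code{\link{force_displacement_curve}}.
#' @param path CSV path.
#' @export
write_curve <- function(curve, path) {
  write.csv(data.frame(displacement_mm = curve$displacement_mm,
                       force_N = curve$force_N),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- read.csv(path)
  force_displacement_curve(df$displacement_mm, df$force_N)
}
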