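#' Specification of the scaled whole-tibia phantom
#'
#' A desk-scale stand-in for a rat tibia scan: a distal-to-proximal volume
#' holding (from distal to proximal) a cortical diaphysis annulus, a tapering
#' metaphyseal cortical shell enclosing a trabecular plate lattice, a solid
#' growth-plate disc, and a short epiphyseal shell; plus two cylindrical
#' hydroxyapatite calibration inserts of distinct uniform grayscale standing
#' in the surrounding air. The default total length is 10 mm (a real rat
#' tibia is about 40 mm; the scale is a knob) so that thickness mapping and
#' the micro-FE solve stay desk-scale.
#'
#' @param total_length bone length L, mm (distal end to proximal end).
#' @param voxel_size isotropic voxel size, mm.
#' @param r_outer_diaphysis,r_inner_diaphysis mid-shaft annulus radii, mm.
#' @param r_outer_metaphysis,r_inner_metaphysis metaphyseal shell radii, mm.
#' @param metaphysis_length length of the trabecular compartment, mm.
#' @param taper_length length of the metaphysis-to-diaphysis taper, mm.
#' @param growth_plate_offset distance from the proximal bone end to the
#'   growth-plate disc, mm.
#' @param growth_plate_thickness thickness of the solid disc, mm.
#' @param plate_thickness,plate_gap trabecular plate lattice geometry, mm.
#' @param trab_clearance marrow gap kept between lattice and shell, mm
#'   (wide enough that the shell-exclusion closing step cannot bridge it).
#' @param insert_radius calibration insert radius, mm.
#' @param grayscale_insert_low,grayscale_insert_high uniform grayscales of
#'   the 0.25 and 0.75 g/cm3 CaHA inserts.
#' @inheritParams phantom_spec
#' @return a \code{tibia_spec}.
#' @export
tibia_spec <- function(total_length = 10, voxel_size = 0.018,
                       r_outer_diaphysis = 0.9, r_inner_diaphysis = 0.55,
                       r_outer_metaphysis = 1.3, r_inner_metaphysis = 1.05,
                       metaphysis_length = 2.0, taper_length = 1.0,
                       growth_plate_offset = 0.8,
                       growth_plate_thickness = 0.15,
                       plate_thickness = 0.108, plate_gap = 0.324,
                       trab_clearance = 0.2,
                       insert_radius = 0.25,
                       grayscale_bone = 160, grayscale_background = 30,
                       grayscale_insert_low = 80, grayscale_insert_high = 130,
                       noise_sd = 0, seed = 1L, margin = 0.2) {
  spec <- as.list(environment())
  with(spec, {
    stopifnot(total_length > 0, voxel_size > 0,
              r_inner_diaphysis < r_outer_diaphysis,
              r_inner_metaphysis < r_outer_metaphysis,
              growth_plate_offset + growth_plate_thickness +
                metaphysis_length + taper_length < total_length,
              grayscale_bone > grayscale_background,
              noise_sd >= 0)
  })
  structure(spec, class = "tibia_spec")
}

#' Generate the scaled whole-tibia phantom
#'
#' Voxelises a \code{\link{tibia_spec}} by voxel-centre sampling and returns
#' the noisy volume (landmarks filled in), plus noise-free region labels that
#' downstream tests can use as independent ground truth: the bone membership
#' mask, the trabecular-lattice mask, the trabecular compartment (the marrow
#' cylinder that the lattice occupies), the cortical bone mask, and the two
#' insert masks.
#'
#' Axis convention: z runs distal (slice 1) to proximal; the bone occupies
#' \code{margin} to \code{margin + total_length} along z.
#'
#' @param spec a \code{\link{tibia_spec}}.
#' @return list with \code{volume}, \code{labels} (list of logical arrays)
#'   and \code{landmarks} (also stored in the volume).
#' @export
generate_full_tibia <- function(spec = tibia_spec()) {
  stopifnot(inherits(spec, "tibia_spec"))
  vs <- spec$voxel_size
  L <- spec$total_length

  half_width <- spec$r_outer_metaphysis + 2 * spec$insert_radius + 3 * spec$margin
  nx <- ny <- round(2 * half_width / vs)
  nz <- round((L + 2 * spec$margin) / vs)
  .check_volume_size(c(nx, ny, nz))

  cx <- nx * vs / 2; cy <- ny * vs / 2
  xs <- .centres(nx, vs) - cx
  ys <- .centres(ny, vs) - cy
  zs <- .centres(nz, vs)
  r2 <- outer(xs^2, ys^2, "+")
  r <- sqrt(r2)

  z_distal <- spec$margin                 # distal end of the bone, mm
  z_prox <- z_distal + L                  # proximal end, mm
  z_gp <- z_prox - spec$growth_plate_offset          # growth-plate top, mm
  z_gp_bot <- z_gp - spec$growth_plate_thickness
  z_meta_bot <- z_gp_bot - spec$metaphysis_length
  z_taper_bot <- z_meta_bot - spec$taper_length

  # outer/inner shell radii as a function of z (linear taper between levels)
  radii_at <- function(z) {
    f <- function(lo, hi) {  # interpolate metaphysis <-> diaphysis
      if (z >= z_meta_bot) hi
      else if (z <= z_taper_bot) lo
      else lo + (hi - lo) * (z - z_taper_bot) / spec$taper_length
    }
    c(outer = f(spec$r_outer_diaphysis, spec$r_outer_metaphysis),
      inner = f(spec$r_inner_diaphysis, spec$r_inner_metaphysis))
  }

  bone <- array(FALSE, c(nx, ny, nz))
  cortical <- array(FALSE, c(nx, ny, nz))
  trab <- array(FALSE, c(nx, ny, nz))
  compartment <- array(FALSE, c(nx, ny, nz))

  period <- spec$plate_thickness + spec$plate_gap
  in_plate_x <- .in_periodic_slab(xs + cx, 0, period, spec$plate_thickness)
  # z-normal cross-plates keep the lattice face-connected along z
  in_plate_z <- .in_periodic_slab(zs, 0, 3 * period, spec$plate_thickness)

  for (k in seq_len(nz)) {
    z <- zs[k]
    if (z < z_distal || z > z_prox) next
    rad <- radii_at(z)
    shell <- r2 >= rad["inner"]^2 & r2 <= rad["outer"]^2
    if (z >= z_gp_bot && z <= z_gp) {
      # growth plate: solid disc
      disc <- r2 <= rad["outer"]^2
      bone[, , k] <- disc
      cortical[, , k] <- disc
      next
    }
    slice <- shell
    cortical[, , k] <- shell
    if (z >= z_meta_bot && z < z_gp_bot) {
      # trabecular compartment: lattice inside the shell, with clearance
      inside <- r <= (rad["inner"] - spec$trab_clearance)
      lat <- inside & (outer(in_plate_x, rep(TRUE, ny)) | in_plate_z[k])
      slice <- slice | lat
      trab[, , k] <- lat
      compartment[, , k] <- inside
    }
    bone[, , k] <- slice
  }

  # calibration inserts: z-aligned cylinders in air, full bone z-extent
  ins_off <- spec$r_outer_metaphysis + spec$insert_radius + spec$margin
  low2 <- outer((xs - ins_off)^2, ys^2, "+") <= spec$insert_radius^2
  high2 <- outer((xs + ins_off)^2, ys^2, "+") <= spec$insert_radius^2
  zspan <- zs >= z_distal & zs <= z_prox
  insert_low <- array(FALSE, c(nx, ny, nz))
  insert_high <- array(FALSE, c(nx, ny, nz))
  for (k in which(zspan)) {
    insert_low[, , k] <- low2
    insert_high[, , k] <- high2
  }

  gs <- array(spec$grayscale_background, c(nx, ny, nz))
  gs[insert_low] <- spec$grayscale_insert_low
  gs[insert_high] <- spec$grayscale_insert_high
  gs[bone] <- spec$grayscale_bone
  gs <- .apply_noise(gs, spec$noise_sd, spec$seed)

  landmarks <- list(
    growth_plate_z = which.min(abs(zs - z_gp_bot)),
    total_length_L = L,
    distal_end_z = which(zs >= z_distal)[1],
    anteroposterior_axis = "y")

  list(volume = image_volume(gs, vs, landmarks),
       labels = list(bone = bone, cortical = cortical, trabecular = trab,
                     trabecular_compartment = compartment,
                     insert_low = insert_low, insert_high = insert_high),
       landmarks = landmarks)
}
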