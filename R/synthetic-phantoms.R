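#' Specification of a geometric bone phantom
#'
#' Describes an analytic solid to be voxelised into an \code{\link{image_volume}}
#' together with closed-form ground truth for the morphometric parameters the
#' geometry determines. Membership is decided by voxel-centre sampling (a
#' voxel is bone iff its centre lies inside the solid), which keeps the
#' analytic oracles exact up to digitisation.
#'
#' Kinds and their geometry fields (all lengths mm):
#' \itemize{
#' \item \code{annulus_diaphysis}: \code{r_outer}, \code{r_inner}, \code{length};
#'   a hollow cylinder along z, the cortical mid-shaft stand-in.
#' \item \code{plate_lattice}: \code{plate_thickness}, \code{plate_gap},
#'   \code{side}; parallel plates normal to x filling a cube, the trabecular
#'   plate stand-in.
#' \item \code{rod_lattice}: \code{rod_diameter}, \code{rod_spacing},
#'   \code{side}; a square array of z-aligned rods, the trabecular rod
#'   stand-in.
#' \item \code{uniform_block}: \code{side} (or \code{dims}, length 3); solid bone.
#' }
#'
#' @param kind one of the phantom kinds above.
#' @param voxel_size isotropic voxel size, mm.
#' @param grayscale_bone,grayscale_background 8-bit grayscale assigned to
#'   bone / background voxels before noise.
#' @param noise_sd additive Gaussian noise SD in grayscale units; the noisy
#'   image is clipped to [0, 255].
#' @param seed integer seed for the noise stream.
#' @param margin background margin around the solid, mm.
#' @param ... geometry fields for the chosen kind (see above).
#' @return a \code{phantom_spec}.
#' @export
phantom_spec <- function(kind = c("annulus_diaphysis", "plate_lattice",
                                  "rod_lattice", "uniform_block"),
                         voxel_size = 0.018,
                         grayscale_bone = 160, grayscale_background = 30,
                         noise_sd = 0, seed = 1L, margin = 0.1, ...) {
  kind <- match.arg(kind)
  geom <- list(...)
  defaults <- switch(kind,
    annulus_diaphysis = list(r_outer = 1.0, r_inner = 0.5, length = 0.9),
    plate_lattice     = list(plate_thickness = 0.054, plate_gap = 0.090,
                             side = 1.152),
    rod_lattice       = list(rod_diameter = 0.09, rod_spacing = 0.324,
                             side = 1.296),
    uniform_block     = list(side = 0.9))
  bad <- setdiff(names(geom), names(defaults))
  if (length(bad)) stop("unknown geometry field(s) for ", kind, ": ",
                        paste(bad, collapse = ", "))
  defaults[names(geom)] <- geom
  spec <- c(list(kind = kind, voxel_size = voxel_size,
                 grayscale_bone = grayscale_bone,
                 grayscale_background = grayscale_background,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 margin = margin), defaults)
  with(spec, {
    stopifnot(voxel_size > 0, noise_sd >= 0, margin >= 0,
              grayscale_bone > grayscale_background,
              grayscale_bone <= 255, grayscale_background >= 0)
  })
  lens <- unlist(spec[setdiff(names(defaults), "dims")])
  if (any(lens <= 0)) stop("all phantom lengths must be positive")
  if (kind == "annulus_diaphysis" && spec$r_inner >= spec$r_outer)
    stop("inner radius must be smaller than outer radius")
  if (kind == "rod_lattice" && spec$rod_diameter >= spec$rod_spacing)
    stop("rod diameter must be smaller than rod spacing")
  structure(spec, class = "phantom_spec")
}

# voxel-centre coordinates along one axis: n voxels of size vs starting at 0
.centres <- function(n, vs) (seq_len(n) - 0.5) * vs

# periodic slab membership with a 1e-9 snap so voxel centres that land on a
# slab face (up to floating-point error) are classified consistently
.in_periodic_slab <- function(x, offset, period, t, eps = 1e-9) {
  frac <- (x - offset) %% period
  frac[frac > period - eps] <- 0
  frac < t - eps
}

.check_volume_size <- function(dims) {
  if (prod(dims) > 512^3)
    stop(sprintf("phantom volume %d x %d x %d exceeds the 512^3 voxel budget; coarsen voxel_size or shrink the geometry",
                 dims[1], dims[2], dims[3]))
}

.apply_noise <- function(gs, noise_sd, seed) {
  if (noise_sd > 0) {
    set.seed(seed)
    gs <- gs + rnorm(length(gs), sd = noise_sd)
    gs <- pmin(pmax(gs, 0), 255)
    dim(gs) <- dim(gs)
  }
  gs
}

#' Generate a geometric phantom volume with analytic ground truth
#'
#' Voxelises a \code{\link{phantom_spec}} and returns the noisy grayscale
#' volume together with the closed-form morphometric ground truth of the
#' generating geometry. Ground truth is computed from the analytic solid,
#' never from the digitised image, so it can serve as an independent oracle
#' for the morphometry code. Parameters the geometry does not determine are
#' \code{NA}.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list with \code{volume} (\code{\link{image_volume}}),
#'   \code{bone_mask} (noise-free membership, logical array) and
#'   \code{truth} (named list of analytic parameter values).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vs <- spec$voxel_size
  m <- spec$margin

  truth <- list(BV_TV = NA_real_, Tb_Th = NA_real_, Tb_Sp = NA_real_,
                Tb_N = NA_real_, Tt_Ar = NA_real_, Ct_Ar = NA_real_,
                Ma_Ar = NA_real_, Ps_Pm = NA_real_, Ec_Pm = NA_real_,
                Ct_Th = NA_real_, I_min = NA_real_, I_max = NA_real_,
                I_p = NA_real_, Ecc = NA_real_)

  if (spec$kind == "annulus_diaphysis") {
    ro <- spec$r_outer; ri <- spec$r_inner
    side <- 2 * (ro + m)
    dims <- c(round(side / vs), round(side / vs), round(spec$length / vs))
    .check_volume_size(dims)
    cx <- dims[1] * vs / 2; cy <- dims[2] * vs / 2
    r2 <- outer((.centres(dims[1], vs) - cx)^2, (.centres(dims[2], vs) - cy)^2, "+")
    in_slice <- r2 <= ro^2 & r2 >= ri^2
    mask <- array(in_slice, dims)
    truth$Tt_Ar <- pi * ro^2
    truth$Ma_Ar <- pi * ri^2
    truth$Ct_Ar <- pi * (ro^2 - ri^2)
    truth$Ps_Pm <- 2 * pi * ro
    truth$Ec_Pm <- 2 * pi * ri
    truth$Ct_Th <- ro - ri
    truth$I_min <- truth$I_max <- pi / 4 * (ro^4 - ri^4)
    truth$I_p <- pi / 2 * (ro^4 - ri^4)
    truth$Ecc <- 0
  } else if (spec$kind == "plate_lattice") {
    t <- spec$plate_thickness; g <- spec$plate_gap; period <- t + g
    n <- round(spec$side / vs)
    dims <- c(n, n, n)
    .check_volume_size(dims)
    x <- .centres(n, vs)
    # offset by half a gap so every plate is interior to the volume (only
    # half-gaps touch the x faces); keeps sphere-fitting free of edge bias
    in_plate <- .in_periodic_slab(x, g / 2, period, t)
    mask <- array(rep(in_plate, times = n * n), dims)
    truth$BV_TV <- t / period
    truth$Tb_Th <- t
    truth$Tb_Sp <- g
    truth$Tb_N <- 1 / period
  } else if (spec$kind == "rod_lattice") {
    d <- spec$rod_diameter; s <- spec$rod_spacing
    n <- round(spec$side / vs)
    dims <- c(n, n, n)
    .check_volume_size(dims)
    x <- .centres(n, vs)
    # rod axes at cell midpoints (k + 1/2)s so all rods are interior
    dx <- abs((x %% s) - s / 2)
    r2 <- outer(dx^2, dx^2, "+")
    mask <- array(r2 <= (d / 2 + 1e-9)^2, dims)
    truth$BV_TV <- pi * (d / 2)^2 / s^2
    truth$Tb_Th <- d
    truth$Tb_Sp <- s * sqrt(2) - d   # sphere centred between four rods
    truth$Tb_N <- truth$BV_TV / d
  } else { # uniform_block
    n <- round(spec$side / vs)
    dims <- c(n, n, n)
    .check_volume_size(dims)
    mask <- array(TRUE, dims)
    truth$BV_TV <- 1
  }

  gs <- array(spec$grayscale_background, dims)
  gs[mask] <- spec$grayscale_bone
  gs <- .apply_noise(gs, spec$noise_sd, spec$seed)

  list(volume = image_volume(gs, vs),
       bone_mask = mask,
       truth = truth)
}
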