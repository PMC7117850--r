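#' Local thickness by inscribed-sphere fitting
#'
#' Assigns every foreground voxel the diameter of the largest sphere that
#' lies entirely within the foreground and contains that voxel (the standard
#' model-independent thickness definition). Implementation: an exact
#' Euclidean distance transform gives each candidate centre its
#' centre-to-boundary radius (distance to the nearest background voxel
#' centre minus half a voxel, so a slab of t voxels measures t, not t + 1),
#' and spheres are painted in decreasing radius order so each voxel keeps
#' the largest covering sphere. The result is exact for this definition; a
#' brute-force all-spheres evaluation gives the same map.
#'
#' @param mask logical 3D array (use \code{dim = c(nx, ny, 1)} for 2D).
#' @param voxel_size voxel edge length in mm.
#' @param border how to treat the volume boundary: \code{"ignore"} continues
#'   the structure past the border (right for cropped VOIs and periodic
#'   phantoms), \code{"background"} ends it there.
#' @return list with \code{map} (thickness in mm, 0 outside the foreground)
#'   and \code{mean} (mean over foreground voxels).
#' @export
local_thickness <- function(mask, voxel_size = 1,
                            border = c("ignore", "background")) {
  border <- match.arg(border)
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  if (!any(mask)) stop("local_thickness: empty mask, thickness undefined")
  d2 <- .edt3d_sq(mask, dim(mask), border == "background")
  if (any(!is.finite(d2[mask])))
    stop("local_thickness: mask has no background; thickness undefined")
  rho <- sqrt(d2) - 0.5
  rho[!mask] <- 0
  th <- .paint_thickness(rho, dim(mask)) * voxel_size
  list(map = th, mean = mean(th[mask]))
}

#' Trabecular separation (marrow-space thickness)
#'
#' Local thickness of the non-bone space inside the VOI: the mean diameter
#' of the largest spheres fitting in the marrow.
#'
#' @param trab_mask logical 3D bone mask (full volume shape).
#' @param voi a trabecular \code{\link{voi_spec}}; the computation runs on
#'   the VOI slab with the crop boundary treated as continuation.
#' @param voxel_size mm.
#' @param region optional logical array (full volume shape) restricting the
#'   marrow space, e.g. the compartment inside the endocortical boundary;
#'   without it the whole slab counts as space, which overstates Tb.Sp when
#'   the slab contains extra-osseous air.
#' @return Tb.Sp in mm.
#' @export
tb_sp <- function(trab_mask, voi, voxel_size, region = NULL) {
  slices <- voi_slices(voi)
  space <- !trab_mask[, , slices, drop = FALSE]
  if (!is.null(region)) space <- space & region[, , slices, drop = FALSE]
  if (!any(space)) stop("tb_sp: no marrow space in the VOI")
  th <- local_thickness(space, voxel_size, border = "ignore")
  if (is.null(region)) return(th$mean)
  mean(th$map[space])
}
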