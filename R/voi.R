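#' Volume-of-interest specification
#'
#' A contiguous z-slab of an \code{\link{image_volume}}, half-open in slice
#' indices: slices \code{z_start} to \code{z_end - 1} (1-based) belong to the
#' VOI. \code{derivation} records the offsets used to locate it.
#'
#' @param kind "trabecular" or "cortical".
#' @param z_start,z_end half-open slice range.
#' @param derivation named list of the offsets/spans used.
#' @export
voi_spec <- function(kind, z_start, z_end, derivation = list()) {
  stopifnot(kind %in% c("trabecular", "cortical"), z_start < z_end, z_start >= 1)
  structure(list(kind = kind, z_start = as.integer(z_start),
                 z_end = as.integer(z_end), derivation = derivation),
            class = "voi_spec")
}

#' Slice indices covered by a VOI
#' @param voi a \code{\link{voi_spec}}.
#' @export
voi_slices <- function(voi) voi$z_start:(voi$z_end - 1L)

#' Locate the trabecular (proximal metaphyseal) VOI
#'
#' The VOI targets the secondary spongiosa: it starts 0.35 mm distal to the
#' growth-plate landmark (i.e. toward the diaphysis, away from the joint)
#' and extends distally for 12 percent of the total tibial length L. Offsets
#' are converted to slices by rounding at the volume's voxel size.
#'
#' @param vol an \code{\link{image_volume}} with \code{growth_plate_z} and
#'   \code{total_length_L} landmarks.
#' @param offset_mm distance from the growth plate to the VOI start, mm.
#' @param length_fraction VOI span as a fraction of L.
#' @return a \code{\link{voi_spec}}.
#' @export
locate_trabecular_voi <- function(vol, offset_mm = 0.35, length_fraction = 0.12) {
  stopifnot(inherits(vol, "image_volume"))
  lm <- vol$landmarks
  if (is.null(lm$growth_plate_z) || is.null(lm$total_length_L))
    stop("growth_plate_z and total_length_L landmarks are required")
  vs <- vol$voxel_size
  offset <- round(offset_mm / vs)
  span <- round(length_fraction * lm$total_length_L / vs)
  z_end <- lm$growth_plate_z - offset + 1L   # most proximal slice + 1
  z_start <- z_end - span
  if (z_start < 1 || z_end - 1 > dim(vol$data)[3])
    stop("trabecular VOI falls outside the volume")
  voi_spec("trabecular", z_start, z_end,
           derivation = list(offset_slices = offset, span_slices = span,
                             growth_plate_z = lm$growth_plate_z))
}

#' Locate the cortical (mid-diaphyseal) VOI
#'
#' Centred at the slice lying L/2 from the distal end of the bone, spanning
#' 5 percent of L split equally proximally and distally; when the span is
#' odd the extra slice goes proximal.
#'
#' @param vol an \code{\link{image_volume}} with a \code{total_length_L}
#'   landmark; \code{distal_end_z} defaults to slice 1.
#' @param length_fraction VOI span as a fraction of L.
#' @return a \code{\link{voi_spec}}.
#' @export
locate_cortical_voi <- function(vol, length_fraction = 0.05) {
  stopifnot(inherits(vol, "image_volume"))
  lm <- vol$landmarks
  if (is.null(lm$total_length_L))
    stop("total_length_L landmark is required")
  vs <- vol$voxel_size
  distal <- if (is.null(lm$distal_end_z)) 1L else lm$distal_end_z
  centre <- distal + round(0.5 * lm$total_length_L / vs)
  span <- round(length_fraction * lm$total_length_L / vs)
  # inclusive range [centre - floor(span/2) + 1, centre + ceiling(span/2)]:
  # the odd slice lands on the proximal side
  z_start <- centre - span %/% 2 + 1L
  z_end <- centre + as.integer(ceiling(span / 2)) + 1L
  if (z_start < 1 || z_end - 1 > dim(vol$data)[3])
    stop("cortical VOI falls outside the volume")
  voi_spec("cortical", z_start, z_end,
           derivation = list(centre_z = centre, span_slices = span,
                             distal_end_z = distal))
}

#' Separate trabecular bone from the cortical shell
#'
#' Slice-wise marrow detection: each VOI slice's bone mask is
#' morphologically closed with a disc (sealing cortical pores), the marrow
#' is taken as the largest enclosed background component of the closed mask
#' (largest connected background region not touching the image border), and
#' trabecular bone is the original bone inside the marrow region's filled
#' hull; everything else is shell. Slices without a closed cortical ring
#' (no enclosed background) fall back to a 3D connected-component split:
#' bone connected to the largest component is shell, the rest trabecular.
#'
#' @param mask logical 3D bone mask (from \code{\link{segment_threshold}}).
#' @param voi trabecular \code{\link{voi_spec}}.
#' @param voxel_size mm, used to convert the closing radius.
#' @param r_close_mm closing-disc radius in mm (default 0.09, about the
#'   scale of cortical pores; the value is a stand-in for an unpublished
#'   semiautomatic step and is deliberately exposed).
#' @return list of logical arrays \code{trab_mask}, \code{shell_mask}
#'   (full volume shape, non-VOI slices all FALSE), and
#'   \code{flagged_slices} (z indices that used the 3D fallback).
#' @export
exclude_cortical_shell <- function(mask, voi, voxel_size, r_close_mm = 0.09) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3, inherits(voi, "voi_spec"))
  dims <- dim(mask)
  slices <- voi_slices(voi)
  stopifnot(max(slices) <= dims[3])
  r_vox <- max(1L, round(r_close_mm / voxel_size))
  brush <- EBImage::makeBrush(2L * r_vox + 1L, shape = "disc")

  trab <- array(FALSE, dims)
  shell <- array(FALSE, dims)
  flagged <- integer()

  for (z in slices) {
    bone2d <- mask[, , z]
    if (!any(bone2d)) next
    closed <- EBImage::closing(bone2d * 1, brush) > 0
    bg <- EBImage::bwlabel(!closed)
    border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    border_labels <- border_labels[border_labels > 0]
    inner <- bg
    inner[inner %in% border_labels] <- 0L
    if (!any(inner > 0)) { flagged <- c(flagged, z); next }
    sizes <- tabulate(inner[inner > 0L])
    marrow <- inner == which.max(sizes)
    marrow_hull <- EBImage::fillHull(marrow * 1) > 0
    trab[, , z] <- bone2d & marrow_hull
    shell[, , z] <- bone2d & !marrow_hull
  }

  if (length(flagged)) {
    warning("no closed cortical ring in slice(s) ",
            paste(flagged, collapse = ", "), "; using 3D component fallback")
    sub <- mask[, , slices, drop = FALSE]
    main <- largest_component(sub, 6)
    for (z in flagged) {
      k <- match(z, slices)
      bone2d <- mask[, , z]
      shell[, , z] <- bone2d & main[, , k]
      trab[, , z] <- bone2d & !main[, , k]
    }
  }

  list(trab_mask = trab, shell_mask = shell, flagged_slices = flagged)
}
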