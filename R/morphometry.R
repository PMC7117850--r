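#' Bone volume fraction
#'
#' Bone voxels over total VOI voxels. An optional region mask restricts the
#' denominator (e.g. to the trabecular compartment inside the endocortical
#' boundary instead of the full rectangular slab).
#'
#' @param trab_mask logical 3D bone mask (full volume shape).
#' @param voi a \code{\link{voi_spec}}.
#' @param region optional logical array (full volume shape); when given,
#'   BV/TV = bone inside region / region voxels, within the VOI slices.
#' @return fraction in [0, 1].
#' @export
bv_tv <- function(trab_mask, voi, region = NULL) {
  slices <- voi_slices(voi)
  bone <- trab_mask[, , slices, drop = FALSE]
  if (is.null(region)) return(sum(bone) / length(bone))
  reg <- region[, , slices, drop = FALSE]
  if (!any(reg)) stop("bv_tv: empty region")
  sum(bone & reg) / sum(reg)
}

#' Trabecular number
#'
#' Direct-model convention Tb.N = (BV/TV) / Tb.Th: struts per unit length
#' consistent with the measured volume fraction and mean thickness. (For a
#' parallel-plate lattice this reduces to 1 / (thickness + gap).)
#'
#' @param bvtv bone volume fraction.
#' @param tbth mean trabecular thickness, mm.
#' @return Tb.N in 1/mm.
#' @export
tb_n <- function(bvtv, tbth) {
  if (bvtv == 0) return(0)
  if (!(tbth > 0)) stop("tb_n: Tb.Th must be positive when bone is present")
  bvtv / tbth
}

#' Mean calibrated density over a region
#'
#' Applies a phantom density calibration to the grayscale values of a region
#' and averages. BMD uses the whole VOI (bone plus marrow); TMD uses bone
#' voxels only.
#'
#' @param vol an \code{\link{image_volume}}.
#' @param region logical array (full volume shape) or a \code{\link{voi_spec}}
#'   (meaning: every voxel in the VOI slab).
#' @param map a \code{\link{fit_phantom_map}} calibration.
#' @return mean density, g/cm^3.
#' @export
mean_density <- function(vol, region, map) {
  stopifnot(inherits(vol, "image_volume"), inherits(map, "phantom_density_map"))
  gs <- if (inherits(region, "voi_spec")) {
    vol$data[, , voi_slices(region)]
  } else {
    stopifnot(is.logical(region))
    if (!any(region)) stop("mean_density: empty region")
    vol$data[region]
  }
  mean(map(gs))
}

#' Trabecular morphometry of a segmented VOI
#'
#' Computes the trabecular parameter set: BMD (phantom-calibrated mean
#' density over the entire VOI, bone + marrow), BV/TV, Tb.Th, Tb.Sp and
#' Tb.N.
#'
#' @param vol an \code{\link{image_volume}}.
#' @param trab_mask logical trabecular bone mask (shell already excluded).
#' @param voi trabecular \code{\link{voi_spec}}.
#' @param map optional \code{\link{fit_phantom_map}}; BMD is NA without it.
#' @param region optional denominator region for BV/TV and BMD (see
#'   \code{\link{bv_tv}}).
#' @return named list of class \code{trabecular_metrics}.
#' @export
trabecular_metrics <- function(vol, trab_mask, voi, map = NULL, region = NULL) {
  slices <- voi_slices(voi)
  bone <- trab_mask[, , slices, drop = FALSE]
  bvtv <- bv_tv(trab_mask, voi, region)
  if (any(bone)) {
    th <- local_thickness(bone, vol$voxel_size, border = "ignore")$mean
    sp <- tb_sp(trab_mask, voi, vol$voxel_size, region)
    tbn <- tb_n(bvtv, th)
  } else {
    th <- NA_real_; sp <- NA_real_; tbn <- 0
  }
  bmd <- if (is.null(map)) NA_real_ else {
    if (is.null(region)) mean_density(vol, voi, map) else {
      reg <- array(FALSE, dim(vol$data)); reg[, , slices] <- region[, , slices]
      mean_density(vol, reg, map)
    }
  }
  structure(list(BMD = bmd, BV_TV = bvtv, Tb_Th = th, Tb_Sp = sp, Tb_N = tbn),
            class = "trabecular_metrics")
}

# shoelace area (signed) and perimeter of a closed polyline
.poly_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}
.poly_length <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(sqrt((x - x[j])^2 + (y - y[j])^2))
}

# largest-|area| contour of a binary slice at the 0.5 level (marching squares
# via grDevices::contourLines); a light Gaussian smoothing of the indicator
# field removes the ~6% staircase overestimate of smooth perimeters (the
# level set of a smoothed step edge stays on the edge, so areas are
# unbiased to first order); falls back to the raw field when smoothing
# erases a tiny region. Returns NULL when no contour exists.
.outer_contour <- function(m, xs, ys, sigma = 1) {
  field <- if (sigma > 0) EBImage::gblur(m * 1, sigma = sigma) else m * 1
  cl <- contourLines(xs, ys, field, levels = 0.5)
  if (!length(cl) && sigma > 0) cl <- contourLines(xs, ys, m * 1, levels = 0.5)
  if (!length(cl)) return(NULL)
  areas <- vapply(cl, function(cc) abs(.poly_area(cc$x, cc$y)), 0)
  cl[[which.max(areas)]]
}

#' Cross-sectional (cortical) geometry of a VOI
#'
#' Per-slice analysis of the mid-diaphyseal section, averaged over the VOI:
#' areas inside the periosteal and endocortical envelopes (sub-voxel
#' marching-squares contours at the 0.5 level), cortical bone area from the
#' voxel count, contour perimeters, principal second moments of area of the
#' bone region (I_min, I_max; polar moment I_p = I_min + I_max by
#' definition), ellipse-equivalent eccentricity sqrt(1 - I_min/I_max),
#' 2D local thickness of the ring (Ct.Th), the centroid-to-outermost
#' periosteal distance c_max, and the section width along the designated
#' anteroposterior axis (b_ap).
#'
#' Slices whose cortical ring is broken (no enclosed marrow, but one appears
#' after a small morphological closing) are excluded with a warning; solid
#' sections are analysed with Ma.Ar = 0.
#'
#' @param cort_mask logical 3D bone mask (full volume shape).
#' @param voi cortical \code{\link{voi_spec}}.
#' @param voxel_size mm.
#' @param ap_axis which image axis is anteroposterior, "x" or "y".
#' @return list of class \code{cortical_metrics}: across-slice means of the
#'   geometry fields plus \code{per_slice} (data.frame) and
#'   \code{excluded_slices}.
#' @export
section_properties <- function(cort_mask, voi, voxel_size, ap_axis = "y") {
  stopifnot(is.logical(cort_mask), length(dim(cort_mask)) == 3,
            ap_axis %in% c("x", "y"))
  vs <- voxel_size
  slices <- voi_slices(voi)
  nx <- dim(cort_mask)[1]; ny <- dim(cort_mask)[2]
  xs <- .centres(nx, vs); ys <- .centres(ny, vs)
  brush <- EBImage::makeBrush(11L, shape = "disc")

  rows <- list(); excluded <- integer()
  for (z in slices) {
    m <- cort_mask[, , z]
    if (!any(m)) { excluded <- c(excluded, z); next }
    filled <- EBImage::fillHull(m * 1) > 0
    marrow <- filled & !m
    if (!any(marrow)) {
      # solid or broken ring? a broken ring closes into one under closing
      closed <- EBImage::closing(m * 1, brush) > 0
      cl_filled <- EBImage::fillHull(closed * 1) > 0
      if (any(cl_filled & !closed)) { excluded <- c(excluded, z); next }
    }

    outer_c <- .outer_contour(filled, xs, ys)
    if (is.null(outer_c)) { excluded <- c(excluded, z); next }
    tt_ar <- abs(.poly_area(outer_c$x, outer_c$y))
    ps_pm <- .poly_length(outer_c$x, outer_c$y)

    if (any(marrow)) {
      inner_c <- .outer_contour(marrow, xs, ys)
      ma_ar <- abs(.poly_area(inner_c$x, inner_c$y))
      ec_pm <- .poly_length(inner_c$x, inner_c$y)
    } else { ma_ar <- 0; ec_pm <- 0 }

    ct_ar <- sum(m) * vs^2

    idx <- which(m, arr.ind = TRUE)
    px <- xs[idx[, 1]]; py <- ys[idx[, 2]]
    cx <- mean(px); cy <- mean(py)
    a2 <- vs^2; self <- vs^4 / 12   # per-pixel square's own moment
    Ixx <- sum((py - cy)^2) * a2 + nrow(idx) * self
    Iyy <- sum((px - cx)^2) * a2 + nrow(idx) * self
    Ixy <- sum((px - cx) * (py - cy)) * a2
    avg <- (Ixx + Iyy) / 2
    rad <- sqrt(((Ixx - Iyy) / 2)^2 + Ixy^2)
    i_max <- avg + rad; i_min <- avg - rad

    ct_th <- local_thickness(array(m, c(nx, ny, 1)), vs, border = "background")$mean
    c_max <- max(sqrt((outer_c$x - cx)^2 + (outer_c$y - cy)^2))
    b_ap <- if (ap_axis == "y") diff(range(outer_c$y)) else diff(range(outer_c$x))

    rows[[length(rows) + 1]] <- data.frame(
      z = z, Tt_Ar = tt_ar, Ct_Ar = ct_ar, Ma_Ar = ma_ar,
      Ps_Pm = ps_pm, Ec_Pm = ec_pm, Ct_Th = ct_th,
      I_min = i_min, I_max = i_max, I_p = i_min + i_max,
      Ecc = sqrt(max(0, 1 - i_min / i_max)),
      c_max = c_max, b_ap = b_ap)
  }
  if (!length(rows))
    stop("section_properties: no slice with an analysable cortical section")
  if (length(excluded))
    warning("section_properties: excluded slice(s) ",
            paste(excluded, collapse = ", "))
  per_slice <- do.call(rbind, rows)
  means <- as.list(colMeans(per_slice[setdiff(names(per_slice), "z")]))
  structure(c(means, list(per_slice = per_slice, excluded_slices = excluded)),
            class = "cortical_metrics")
}

#' Cortical morphometry of a segmented VOI
#'
#' Geometry via \code{\link{section_properties}} plus TMD (phantom-calibrated
#' mean density over bone voxels only).
#'
#' @inheritParams section_properties
#' @param vol an \code{\link{image_volume}}.
#' @param map optional \code{\link{fit_phantom_map}}; TMD is NA without it.
#' @export
cortical_metrics <- function(vol, cort_mask, voi, map = NULL, ap_axis = "y") {
  res <- section_properties(cort_mask, voi, vol$voxel_size, ap_axis)
  reg <- array(FALSE, dim(vol$data))
  reg[, , voi_slices(voi)] <- cort_mask[, , voi_slices(voi)]
  res$TMD <- if (is.null(map)) NA_real_ else mean_density(vol, reg, map)
  res
}

#' Tidy one or more metric sets into a long table
#'
#' One row per specimen x parameter, ready for \code{\link{write_study}} or
#' the stats layer.
#'
#' @param metrics a \code{trabecular_metrics} or \code{cortical_metrics}
#'   object (or any named list of scalars; non-scalars are dropped).
#' @param specimen,week identifiers attached to every row.
#' @export
metrics_to_table <- function(metrics, specimen = "specimen", week = NA) {
  keep <- vapply(metrics, function(v) is.numeric(v) && length(v) == 1, TRUE)
  vals <- unlist(metrics[keep])
  data.frame(animal = specimen, week = week,
             parameter = names(vals), value = as.numeric(vals),
             row.names = NULL)
}
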