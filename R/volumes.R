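#' Image volume container
#'
#' A minimal container for an isotropic 3D grayscale micro-CT volume. The
#' array is indexed \code{[x, y, z]}; slice index \code{z} runs along the
#' bone's long axis with the distal end at \code{z = 1} and the proximal end
#' at \code{z = dim(data)[3]}. Grayscale values live on the 8-bit scale
#' 0--255 (stored as numeric so noise and calibration stay exact).
#'
#' @param data numeric 3D array, grayscale in \code{[0, 255]}.
#' @param voxel_size isotropic voxel edge length in mm.
#' @param landmarks optional named list; recognised entries are
#'   \code{growth_plate_z} (slice index of the growth plate) and
#'   \code{total_length_L} (total bone length in mm measured from the distal
#'   end). Further entries are carried through untouched.
#' @return an object of class \code{image_volume}.
#' @export
image_volume <- function(data, voxel_size, landmarks = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    stop("voxel_size must be a single positive number (mm)")
  if (!is.null(landmarks$growth_plate_z)) {
    gz <- landmarks$growth_plate_z
    if (gz < 1 || gz > dim(data)[3])
      stop("growth_plate_z outside the volume's z extent")
  }
  if (!is.null(landmarks$total_length_L)) {
    if (landmarks$total_length_L > dim(data)[3] * voxel_size + 1e-9)
      stop("total_length_L exceeds the volume's z extent")
  }
  structure(list(data = data, voxel_size = voxel_size, landmarks = landmarks),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_volume: %d x %d x %d voxels @ %.4g mm (%.3g x %.3g x %.3g mm)\n",
              d[1], d[2], d[3], x$voxel_size,
              d[1] * x$voxel_size, d[2] * x$voxel_size, d[3] * x$voxel_size))
  if (length(x$landmarks))
    cat("landmarks:", paste(names(x$landmarks),
                            vapply(x$landmarks, function(v) paste(format(v), collapse = ","), ""),
                            sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Write / read an image volume as a multipage TIFF with a JSON sidecar
#'
#' One TIFF page per z slice (distal slice first); the sidecar records the
#' voxel size, the axis order and any landmarks so a round trip is lossless.
#'
#' @param vol an \code{\link{image_volume}}.
#' @param path output TIFF path; the sidecar is written at \code{path} with
#'   extension \code{.json}.
#' @return \code{write_volume} returns \code{path} invisibly;
#'   \code{read_volume} returns an \code{image_volume}.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  d <- dim(vol$data)
  # tiff wants a list of y-by-x matrices in [0,1]
  pages <- lapply(seq_len(d[3]), function(z) t(vol$data[, , z]) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  sidecar <- list(voxel_size_mm = vol$voxel_size,
                  axis_order = "z-y-x pages, distal at page 1",
                  landmarks = vol$landmarks)
  jsonlite::write_json(sidecar, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  data <- array(0, d)
  for (z in seq_along(pages)) data[, , z] <- t(pages[[z]]) * 255
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  vs <- 1; lm <- list()
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    vs <- meta$voxel_size_mm
    lm <- as.list(meta$landmarks)
  }
  image_volume(data, vs, lm)
}

#' Read a NIfTI volume into an image_volume
#'
#' Voxel size is taken from the NIfTI header (first pixdim, mm); landmarks
#' must be supplied by the caller since NIfTI carries none.
#'
#' @param path NIfTI file.
#' @param landmarks see \code{\link{image_volume}}.
#' @export
read_volume_nifti <- function(path, landmarks = list()) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI requires the RNifti package")
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1]
  image_volume(array(as.numeric(img), dim(img)), vs, landmarks)
}

#' Largest connected component of a binary mask
#'
#' Retains the largest 6- or 26-connected foreground component; ties are
#' broken in favour of the component whose first voxel has the lowest linear
#' (x fastest, then y, then z) index.
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (face) or 26 (face+edge+vertex).
#' @return logical array of the same shape.
#' @export
largest_component <- function(mask, connectivity = 6) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3, connectivity %in% c(6, 26))
  if (!any(mask)) return(mask)
  lab <- .label3d(mask, dim(mask), as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes) # which.max takes the first (lowest label) on ties
  array(lab == keep, dim(mask))
}
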