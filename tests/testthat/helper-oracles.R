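# Independent oracles and shared fixtures for the test suite.

# Brute-force all-spheres local thickness (pure R, independent of the
# package's distance-transform + painting route). For every foreground
# voxel q the largest inscribed ball radius is found by exhaustive search
# over background voxels (centre-to-surface convention: distance to the
# nearest background centre minus half a voxel; out-of-bounds is treated as
# foreground), then every voxel records the diameter of the largest ball
# covering it.
brute_force_thickness <- function(mask, voxel_size = 1) {
  dims <- dim(mask)
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  if (nrow(bg) == 0) stop("no background")
  rho <- numeric(nrow(fg))
  for (i in seq_len(nrow(fg))) {
    d2 <- (bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2 + (bg[, 3] - fg[i, 3])^2
    rho[i] <- sqrt(min(d2)) - 0.5
  }
  th <- array(0, dims)
  for (i in seq_len(nrow(fg))) {
    d2 <- (fg[, 1] - fg[i, 1])^2 + (fg[, 2] - fg[i, 2])^2 + (fg[, 3] - fg[i, 3])^2
    covered <- d2 <= rho[i]^2
    diam <- 2 * rho[i]
    idx <- fg[covered, , drop = FALSE]
    lin <- idx[, 1] + dims[1] * ((idx[, 2] - 1) + dims[2] * (idx[, 3] - 1))
    th[lin] <- pmax(th[lin], diam)
  }
  th * voxel_size
}

# random connected-ish blob masks from thresholded smoothed noise
random_blob_mask <- function(seed, n = 32, fill = 0.2) {
  set.seed(seed)
  noise <- array(rnorm(n^3), c(n, n, n))
  sm <- EBImage::gblur(noise, sigma = 2)
  array(sm > quantile(sm, 1 - fill), c(n, n, n))
}

# trapezoidal (consistent) nodal weights for a uniform traction on a
# rectangular element face grid
face_weights <- function(model, nodes) {
  xy <- model$node_grid[nodes, c("x", "y"), drop = FALSE]
  wx <- ifelse(xy[, 1] %in% range(xy[, 1]), 0.5, 1)
  wy <- ifelse(xy[, 2] %in% range(xy[, 2]), 0.5, 1)
  wx * wy
}

# grayscale whose HU-chain density maps to a target modulus
grayscale_for_modulus <- function(E, consts = calibration_constants()) {
  rho <- consts$rho_max * sqrt(E / consts$E_max)
  hu <- (rho - consts$rho_intercept) / consts$rho_slope
  (hu - consts$hu_intercept) / consts$hu_slope
}

# uniform prism model of given element counts and modulus
prism_model <- function(nx = 10, ny = 10, nz = 20, E = 10, voxel = 0.018,
                        consts = calibration_constants()) {
  g <- array(grayscale_for_modulus(E, consts), c(2 * nx, 2 * ny, 2 * nz))
  build_mesh(image_volume(g, voxel), consts)
}

# frictionless-support uniaxial compression: bottom fixed in Z, rigid-body
# motion removed, consistent top loads totalling `force` (N, downward)
solve_prism_compression <- function(model, force = 1, tol = 1e-10) {
  zt <- max(model$node_grid[, "z"])
  top <- which(model$node_grid[, "z"] == zt)
  bot <- which(model$node_grid[, "z"] == 0)
  w <- face_weights(model, top)
  loads <- data.frame(node = top, axis = 3L, value = -force * w / sum(w))
  corner <- bot[which(model$node_grid[bot, "x"] == 0 &
                      model$node_grid[bot, "y"] == 0)[1]]
  along_y <- bot[which(model$node_grid[bot, "x"] == 0 &
                       model$node_grid[bot, "y"] == max(model$node_grid[bot, "y"]))[1]]
  dir <- rbind(data.frame(node = bot, axis = 3L, value = 0),
               data.frame(node = corner, axis = 1L, value = 0),
               data.frame(node = corner, axis = 2L, value = 0),
               data.frame(node = along_y, axis = 1L, value = 0))
  solve_fe(model, dirichlet = dir, loads = loads, tol = tol)
}

# ideal three-point-bending curve of a linearly elastic, elastic-perfectly
# bilinear beam with known tissue properties
ideal_beam_curve <- function(E = 20, I = 2, L = 18, sigma_y = 150,
                             c_max = 1.2, postyield_frac = 0.1,
                             ultimate_over_yield = 1.4) {
  k <- 48 * E * 1000 * I / L^3          # N/mm (E GPa -> MPa)
  F_y <- sigma_y * 4 * I / (L * c_max)  # invert sigma = F L c / (4 I)
  curve_spec(stiffness_k = k, yield_force = F_y,
             postyield_slope = postyield_frac * k,
             ultimate_force = ultimate_over_yield * F_y,
             sampling_interval_mm = F_y / k / 200, noise_sd = 0)
}
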