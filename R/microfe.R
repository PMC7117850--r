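# Local node order of the 8-node brick: binary (x fastest) corner offsets.
.hex_corners <- as.matrix(expand.grid(dx = 0:1, dy = 0:1, dz = 0:1))

# isotropic elasticity matrix (Voigt order xx, yy, zz, xy, yz, zx),
# engineering shear strains
.elastic_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3] <- D[1:3, 1:3] + lam
  D
}

# shape-function gradients w.r.t. x,y,z at natural coords xi (length 3),
# for a cube of edge `side`: 8 x 3 matrix
.hex_dN <- function(xi, side) {
  s <- 2 * .hex_corners - 1  # corner signs in {-1, 1}
  dN <- matrix(0, 8, 3)
  for (i in 1:8) {
    f <- (1 + s[i, ] * xi) / 2
    dN[i, 1] <- (s[i, 1] / 2) * f[2] * f[3]
    dN[i, 2] <- f[1] * (s[i, 2] / 2) * f[3]
    dN[i, 3] <- f[1] * f[2] * (s[i, 3] / 2)
  }
  dN * (2 / side)   # d(natural)/d(physical) for the cube
}

# strain-displacement matrix (6 x 24) at natural coords xi
.hex_B <- function(xi, side) {
  dN <- .hex_dN(xi, side)
  B <- matrix(0, 6, 24)
  for (i in 1:8) {
    c0 <- 3 * (i - 1)
    B[1, c0 + 1] <- dN[i, 1]
    B[2, c0 + 2] <- dN[i, 2]
    B[3, c0 + 3] <- dN[i, 3]
    B[4, c0 + 1] <- dN[i, 2]; B[4, c0 + 2] <- dN[i, 1]
    B[5, c0 + 2] <- dN[i, 3]; B[5, c0 + 3] <- dN[i, 2]
    B[6, c0 + 1] <- dN[i, 3]; B[6, c0 + 3] <- dN[i, 1]
  }
  B
}

#' Stiffness matrix of a cubic 8-node brick element
#'
#' Trilinear shape functions, full 2x2x2 Gauss quadrature, isotropic linear
#' elasticity. Degrees of freedom are ordered (node1 x,y,z, node2 x,y,z, ...)
#' with nodes in binary corner order (x fastest). The matrix is symmetric
#' positive-semidefinite with exactly six rigid-body modes and is linear in
#' E, so callers can cache K(E = 1) and scale.
#'
#' @param E Young's modulus (any unit; output follows).
#' @param nu Poisson's ratio, in (0, 0.5).
#' @param side element edge length, mm.
#' @return 24 x 24 matrix. Units: E in GPa and side in mm give N/um-scale
#'   stiffness times 1e-3; with consistent units (force = E-unit x mm^2).
#' @export
hex_stiffness <- function(E, nu, side) {
  stopifnot(E > 0, nu > 0, nu < 0.5, side > 0)
  D <- .elastic_D(E, nu)
  gp <- 1 / sqrt(3)
  K <- matrix(0, 24, 24)
  detJ <- (side / 2)^3
  for (gx in c(-gp, gp)) for (gy in c(-gp, gp)) for (gz in c(-gp, gp)) {
    B <- .hex_B(c(gx, gy, gz), side)
    K <- K + t(B) %*% D %*% B * detJ
  }
  (K + t(K)) / 2
}

#' Build a voxel-based micro-FE mesh from a calibrated volume
#'
#' Aggregates 2x2x2 voxel blocks into cubic brick elements (36 um side at
#' the native 18 um resolution). An element exists iff at least
#' \code{occupancy} of its 8 child voxels are bone at the global threshold;
#' its density is the mean of all 8 children's HU-chain densities, each
#' clamped to [0, rho_max], and its modulus follows the quadratic power law.
#' Finally only the largest face-connected element component is kept.
#'
#' @param vol an \code{\link{image_volume}}.
#' @param consts \code{\link{calibration_constants}}.
#' @param occupancy minimum bone children per element (default 4, majority).
#' @return an \code{fe_model}: element grid (\code{occupied}), per-element
#'   \code{density} and \code{modulus} vectors (grid order), node ids,
#'   element-to-node incidence, element \code{side} in mm.
#' @export
build_mesh <- function(vol, consts = calibration_constants(), occupancy = 4) {
  stopifnot(inherits(vol, "image_volume"))
  d <- dim(vol$data)
  de <- d %/% 2L
  if (any(de == 0)) stop("volume too small to aggregate 2x2x2 voxels")
  gs <- vol$data[seq_len(2 * de[1]), seq_len(2 * de[2]), seq_len(2 * de[3])]
  bone <- gs >= consts$threshold_grayscale
  rho <- pmin(pmax(hu_to_density(grayscale_to_hu(gs, consts), consts), 0),
              consts$rho_max)
  dim(rho) <- dim(gs)

  # per-element sums over the 2x2x2 children
  block_sum <- function(a) {
    a <- a[seq(1, 2 * de[1], 2), , , drop = FALSE] +
         a[seq(2, 2 * de[1], 2), , , drop = FALSE]
    a <- a[, seq(1, 2 * de[2], 2), , drop = FALSE] +
         a[, seq(2, 2 * de[2], 2), , drop = FALSE]
    a[, , seq(1, 2 * de[3], 2), drop = FALSE] +
      a[, , seq(2, 2 * de[3], 2), drop = FALSE]
  }
  nbone <- block_sum(bone * 1)
  occ <- nbone >= occupancy
  if (!any(occ)) stop("build_mesh: no occupied elements at this threshold")
  occ <- largest_component(array(occ, de), 6)

  dens <- block_sum(rho) / 8
  density <- dens[occ]
  modulus <- density_to_modulus(density, consts)

  # node lattice implicit from occupied elements
  eidx <- which(occ, arr.ind = TRUE)
  nnod <- de + 1L
  node_lin <- function(ix, iy, iz) ix + nnod[1] * ((iy - 1L) + nnod[2] * (iz - 1L))
  e2n <- matrix(0L, nrow(eidx), 8)
  for (i in 1:8) {
    e2n[, i] <- node_lin(eidx[, 1] + .hex_corners[i, 1],
                         eidx[, 2] + .hex_corners[i, 2],
                         eidx[, 3] + .hex_corners[i, 3])
  }
  used <- sort(unique(as.vector(e2n)))
  remap <- integer(prod(nnod))
  remap[used] <- seq_along(used)
  e2n <- matrix(remap[e2n], nrow(eidx), 8)

  # node coordinates in element-grid units (corner of element (1,1,1) is 0)
  uz <- (used - 1L) %/% (nnod[1] * nnod[2])
  rem <- (used - 1L) %% (nnod[1] * nnod[2])
  uy <- rem %/% nnod[1]
  ux <- rem %% nnod[1]

  structure(list(
    dims_elem = de, occupied = occ, elem_index = eidx,
    density = density, modulus = modulus,
    side = 2 * vol$voxel_size, nu = consts$poisson_nu,
    e2n = e2n, n_nodes = length(used),
    node_grid = cbind(x = ux, y = uy, z = uz),
    constraints = NULL, loads = NULL), class = "fe_model")
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf("fe_model: %d brick elements (%.3g mm side), %d nodes\n",
              nrow(x$e2n), x$side, x$n_nodes))
  cat(sprintf("modulus range %.3g - %.3g GPa; %s constraints, %s loads\n",
              min(x$modulus), max(x$modulus),
              if (is.null(x$constraints)) "no" else nrow(x$constraints),
              if (is.null(x$loads)) "no" else nrow(x$loads)))
  invisible(x)
}

#' Apply axial compression boundary conditions
#'
#' The total force is split equally over the proximal-face nodes (the
#' mesh's top z layer) and directed along -Z. Distal-face nodes are
#' constrained in X and Y as specified for the scan-based models, plus Z by
#' default: without any Z support the stated conditions leave the stiffness
#' matrix singular, so full distal fixation (standard micro-FE practice) is
#' the default and \code{bc = "xy_plus_one_z"} pins Z at a single distal
#' node instead (statically determinate variant).
#'
#' @param model an \code{fe_model}.
#' @param force total compressive force, N (default 35).
#' @param bc "fixed" (distal x,y,z) or "xy_plus_one_z".
#' @return the model with \code{constraints} (data.frame node, axis) and
#'   \code{loads} (data.frame node, axis, value in N) filled.
#' @export
apply_compression <- function(model, force = 35, bc = c("fixed", "xy_plus_one_z")) {
  bc <- match.arg(bc)
  zt <- max(model$node_grid[, "z"])
  zb <- min(model$node_grid[, "z"])
  prox <- which(model$node_grid[, "z"] == zt)
  dist <- which(model$node_grid[, "z"] == zb)
  if (!length(prox) || !length(dist))
    stop("apply_compression: missing boundary node sets")
  cons <- rbind(data.frame(node = dist, axis = 1L),
                data.frame(node = dist, axis = 2L))
  cons <- rbind(cons,
                if (bc == "fixed") data.frame(node = dist, axis = 3L)
                else data.frame(node = dist[1], axis = 3L))
  model$constraints <- cons
  model$loads <- data.frame(node = prox, axis = 3L,
                            value = -force / length(prox))
  model$total_force <- force
  model
}

# preconditioned conjugate gradients (Jacobi), deterministic
.pcg <- function(A, b, tol = 1e-8, maxit = 30000) {
  n <- length(b)
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(list(x = numeric(n), iterations = 0L, relres = 0))
  Minv <- 1 / Matrix::diag(A)
  x <- numeric(n)
  r <- b
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    relres <- sqrt(sum(r^2)) / nb
    if (relres <= tol) return(list(x = x, iterations = it, relres = relres))
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(sprintf("PCG did not converge in %d iterations (relative residual %.3g)",
               maxit, relres))
}

# assemble the global sparse stiffness (units: N/mm when E is GPa and side
# mm, after the 1e3 GPa -> N/mm^2-km... we keep E in GPa and side in mm, so
# K is in kN/mm; loads in N are scaled accordingly inside solve_fe)
.assemble_K <- function(model) {
  Kunit <- hex_stiffness(1, model$nu, model$side)
  ne <- nrow(model$e2n)
  dofs <- matrix(0L, ne, 24)
  for (i in 1:8) dofs[, (3 * i - 2):(3 * i)] <-
      cbind(3L * model$e2n[, i] - 2L, 3L * model$e2n[, i] - 1L, 3L * model$e2n[, i])
  ii <- dofs[, rep(1:24, times = 24)]
  jj <- dofs[, rep(1:24, each = 24)]
  xx <- outer(model$modulus, as.vector(Kunit))
  Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj), x = as.vector(xx),
                       dims = rep(3L * model$n_nodes, 2))
}

#' Solve the linear-elastic system
#'
#' Assembles the sparse symmetric stiffness from the per-element moduli and
#' solves with Jacobi-preconditioned conjugate gradients to a relative
#' residual of \code{tol}. Dirichlet values (zero from
#' \code{\link{apply_compression}}, or prescribed via \code{dirichlet}) are
#' eliminated; loads enter the right-hand side.
#'
#' @param model an \code{fe_model} with boundary conditions, unless
#'   \code{dirichlet}/\code{loads} are given here.
#' @param dirichlet optional data.frame (node, axis, value mm) of prescribed
#'   displacements; overrides the model's zero constraints when given.
#' @param loads optional data.frame (node, axis, value N); overrides the
#'   model's loads.
#' @param tol PCG relative-residual tolerance.
#' @param maxit PCG iteration cap.
#' @return list with \code{u} (n_nodes x 3 displacement matrix, mm),
#'   \code{iterations}, \code{relres}.
#' @export
solve_fe <- function(model, dirichlet = NULL, loads = NULL,
                     tol = 1e-8, maxit = 30000) {
  stopifnot(inherits(model, "fe_model"))
  if (is.null(dirichlet)) {
    if (is.null(model$constraints)) stop("model has no boundary conditions")
    dirichlet <- data.frame(node = model$constraints$node,
                            axis = model$constraints$axis, value = 0)
  }
  if (is.null(loads)) loads <- model$loads
  ndof <- 3L * model$n_nodes
  K <- .assemble_K(model)    # E in GPa, side in mm -> stiffness in kN/mm

  f <- numeric(ndof)
  if (!is.null(loads) && nrow(loads))
    f[3L * (loads$node - 1L) + loads$axis] <-
      f[3L * (loads$node - 1L) + loads$axis] + loads$value / 1000  # N -> kN

  fixed_dof <- 3L * (dirichlet$node - 1L) + dirichlet$axis
  if (anyDuplicated(fixed_dof)) {
    keep <- !duplicated(fixed_dof)
    dirichlet <- dirichlet[keep, ]; fixed_dof <- fixed_dof[keep]
  }
  u <- numeric(ndof)
  u[fixed_dof] <- dirichlet$value
  free <- setdiff(seq_len(ndof), fixed_dof)
  if (!length(free)) return(list(u = matrix(u, ncol = 3, byrow = TRUE),
                                 iterations = 0L, relres = 0))
  rhs <- f[free] - as.numeric(K[free, fixed_dof, drop = FALSE] %*% u[fixed_dof])
  sol <- .pcg(K[free, free], rhs, tol = tol, maxit = maxit)
  u[free] <- sol$x
  list(u = matrix(u, ncol = 3, byrow = TRUE),
       iterations = sol$iterations, relres = sol$relres)
}

#' Element centroid strains and principal strains
#'
#' Strain tensors from the trilinear shape-function gradients evaluated at
#' each element centroid, then the per-element principal strains (sorted
#' eigenvalues e1 >= e2 >= e3 of the symmetric tensor), in microstrain.
#'
#' @param model an \code{fe_model}.
#' @param u displacement matrix from \code{\link{solve_fe}} (mm).
#' @return list with \code{tensor} (n_e x 6, Voigt order xx, yy, zz, xy, yz,
#'   zx with engineering shears) and \code{principal} (n_e x 3, microstrain).
#' @export
element_strains <- function(model, u) {
  dN <- .hex_dN(c(0, 0, 0), model$side)   # 8 x 3 at the centroid
  ne <- nrow(model$e2n)
  ux <- matrix(u[model$e2n, 1], ne, 8)
  uy <- matrix(u[model$e2n, 2], ne, 8)
  uz <- matrix(u[model$e2n, 3], ne, 8)
  tensor <- cbind(xx = as.numeric(ux %*% dN[, 1]),
                  yy = as.numeric(uy %*% dN[, 2]),
                  zz = as.numeric(uz %*% dN[, 3]),
                  xy = as.numeric(ux %*% dN[, 2] + uy %*% dN[, 1]),
                  yz = as.numeric(uy %*% dN[, 3] + uz %*% dN[, 2]),
                  zx = as.numeric(uz %*% dN[, 1] + ux %*% dN[, 3]))

  principal <- matrix(0, ne, 3)
  for (e in seq_len(ne)) {
    m <- matrix(c(tensor[e, 1], tensor[e, 4] / 2, tensor[e, 6] / 2,
                  tensor[e, 4] / 2, tensor[e, 2], tensor[e, 5] / 2,
                  tensor[e, 6] / 2, tensor[e, 5] / 2, tensor[e, 3]), 3, 3)
    principal[e, ] <- sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
                           decreasing = TRUE)
  }
  colnames(principal) <- c("e1", "e2", "e3")
  list(tensor = tensor, principal = principal * 1e6)
}

#' Elements lying inside a VOI of the source volume
#'
#' Maps a slice-range \code{\link{voi_spec}} (voxel z indices) to the
#' aggregated element grid: an element is in the VOI iff both voxel slices
#' it spans are.
#'
#' @param model an \code{fe_model}.
#' @param voi a \code{\link{voi_spec}} in voxel slice indices.
#' @return logical vector over elements (grid order).
#' @export
fe_voi_elements <- function(model, voi) {
  ez <- model$elem_index[, 3]
  vox_lo <- 2L * ez - 1L
  vox_hi <- 2L * ez
  vox_lo >= voi$z_start & vox_hi <= voi$z_end - 1L
}

#' Summarise principal strains over a VOI
#'
#' Mean principal tensile strain (mean of e1) and mean principal compressive
#' strain magnitude (mean of |e3|), in microstrain, over the selected
#' elements.
#'
#' @param strains result of \code{\link{element_strains}}.
#' @param elements logical or integer element selector (default: all).
#' @return list with \code{mean_tensile}, \code{mean_compressive} (both
#'   microstrain, positive), \code{n_elements}.
#' @export
strain_summary <- function(strains, elements = NULL) {
  p <- strains$principal
  if (!is.null(elements)) p <- p[elements, , drop = FALSE]
  if (!nrow(p)) stop("strain_summary: no elements selected")
  list(mean_tensile = mean(p[, "e1"]),
       mean_compressive = mean(abs(p[, "e3"])),
       n_elements = nrow(p))
}

#' Export the mesh as an ASCII VTK unstructured grid
#'
#' Hexahedral cells with per-cell modulus and density, viewable in ParaView.
#'
#' @param model an \code{fe_model}.
#' @param path output .vtk path.
#' @export
write_mesh_vtk <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "voxel micro-FE mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID"), con)
  coords <- model$node_grid * model$side
  writeLines(sprintf("POINTS %d double", model$n_nodes), con)
  writeLines(sprintf("%.6g %.6g %.6g", coords[, 1], coords[, 2], coords[, 3]), con)
  ne <- nrow(model$e2n)
  # VTK_VOXEL (11) uses the same binary corner ordering as .hex_corners
  writeLines(sprintf("CELLS %d %d", ne, 9 * ne), con)
  writeLines(apply(model$e2n - 1L, 1, function(r) paste(c(8, r), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("11", ne), con)
  writeLines(sprintf("CELL_DATA %d", ne), con)
  writeLines(c("SCALARS modulus_GPa double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.6g", model$modulus), con)
  writeLines(c("SCALARS density_g_cm3 double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.6g", model$density), con)
  invisible(path)
}
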