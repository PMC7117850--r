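test_that("the brick element is symmetric, rigid-body-clean and linear in E", {
  K1 <- hex_stiffness(1, 0.3, 0.036)
  K2 <- hex_stiffness(2, 0.3, 0.036)
  expect_equal(K2, 2 * K1)
  expect_true(isSymmetric(K1))
  expect_lt(max(abs(rowSums(K1))), 1e-14)
  ev <- eigen(K1, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-10 * max(ev)), 6)  # exactly 6 rigid modes
  expect_true(all(ev > -1e-10 * max(ev)))          # positive semidefinite
})

test_that("element energy under uniform strain matches the continuum identity", {
  side <- 0.036; E <- 5; nu <- 0.3
  eps <- c(1e-3, -2e-4, 5e-4, 3e-4, -1e-4, 2e-4)  # Voigt, engineering shear
  strain <- matrix(c(eps[1], eps[4] / 2, eps[6] / 2,
                     eps[4] / 2, eps[2], eps[5] / 2,
                     eps[6] / 2, eps[5] / 2, eps[3]), 3, 3)
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * side
  u <- t(strain %*% t(corners))
  uvec <- as.vector(t(u))
  energy <- 0.5 * as.numeric(t(uvec) %*% hex_stiffness(E, nu, side) %*% uvec)
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(2 * mu, 3), rep(mu, 3))); D[1:3, 1:3] <- D[1:3, 1:3] + lam
  expect_equal(energy, 0.5 * as.numeric(t(eps) %*% D %*% eps) * side^3,
               tolerance = 1e-12)
})

test_that("mesh building aggregates, clamps and culls as specified", {
  g <- array(grayscale_for_modulus(28.6), c(20, 20, 20))
  m <- build_mesh(image_volume(g, 0.018))
  expect_equal(nrow(m$e2n), 1000)          # 2x2x2 aggregation
  expect_equal(length(unique(m$modulus)), 1)
  expect_equal(m$side, 0.036)

  # a single isolated bone voxel: 1 of 8 children, no element
  g2 <- array(0, c(8, 8, 8)); g2[3, 3, 3] <- 200
  expect_error(build_mesh(image_volume(g2, 0.018)), "no occupied")

  # density above rho_max clamps the modulus at E_max
  g3 <- array(255, c(4, 4, 4))
  m3 <- build_mesh(image_volume(g3, 0.018))
  expect_true(all(m3$modulus <= 28.6 + 1e-12))
  expect_equal(max(m3$modulus), 28.6)
  expect_true(all(m3$modulus > 0))

  # majority rule: 4 of 8 children keeps the element, 3 of 8 drops it
  g4 <- array(0, c(2, 2, 2)); g4[1:2, 1:2, 1] <- 200
  expect_equal(nrow(build_mesh(image_volume(g4, 0.018))$e2n), 1)
  g5 <- array(0, c(2, 2, 2)); g5[1:2, 1, 1] <- 200; g5[1, 2, 1] <- 200
  expect_equal(nrow(suppressWarnings(build_mesh(image_volume(g5, 0.018),
                                                occupancy = 3))$e2n), 1)
  expect_error(build_mesh(image_volume(g5, 0.018), occupancy = 4),
               "no occupied")
})

test_that("compression boundary conditions split the force exactly", {
  m <- prism_model(6, 6, 4)
  m <- apply_compression(m, 35)
  expect_equal(sum(m$loads$value), -35)
  expect_equal(length(unique(m$loads$value)), 1)   # equal split
  expect_equal(nrow(m$loads), 49)                  # 7x7 proximal nodes
  expect_equal(m$loads$value[1], -35 / 49)         # 0.7143 N
  expect_setequal(unique(m$constraints$axis), 1:3) # full distal fixation
  m2 <- apply_compression(m, 35, bc = "xy_plus_one_z")
  expect_equal(sum(m2$constraints$axis == 3), 1)
  # zero force gives the zero solution
  sol0 <- solve_fe(apply_compression(m, 0))
  expect_equal(max(abs(sol0$u)), 0)
})

test_that("a homogeneous prism under consistent loads is in a uniform state", {
  m <- prism_model(6, 6, 12, E = 10)
  sol <- solve_prism_compression(m, force = 1)
  st <- element_strains(m, sol$u)
  A <- (6 * m$side)^2
  eps_zz <- -1e-3 / (A * 10)  # F in kN over A mm^2, E in GPa
  expect_lt(max(abs(st$tensor[, "zz"] - eps_zz)) / abs(eps_zz), 1e-6)
  # principal strains reflect the Poisson expansion
  expect_equal(mean(st$principal[, "e1"]) / -mean(st$principal[, "e3"]), 0.3,
               tolerance = 1e-6)
})

test_that("two layers in series add their compliances (axial, nu ~ 0)", {
  co <- calibration_constants(poisson_nu = 1e-6)
  g <- array(0, c(8, 8, 16))
  g[, , 1:8] <- grayscale_for_modulus(10, co)
  g[, , 9:16] <- grayscale_for_modulus(20, co)
  m <- build_mesh(image_volume(g, 0.018), co)
  sol <- solve_prism_compression(m, force = 1)
  top <- which(m$node_grid[, "z"] == max(m$node_grid[, "z"]))
  L_half <- 4 * m$side; A <- (4 * m$side)^2
  expected <- -1e-3 * L_half / A * (1 / 10 + 1 / 20)
  expect_lt(abs(mean(sol$u[top, 3]) - expected) / abs(expected), 1e-6)
})

test_that("solutions are linear in load and inverse-linear in modulus", {
  m1 <- prism_model(4, 4, 6, E = 7.15)
  s1 <- solve_prism_compression(m1, force = 1, tol = 1e-12)
  s2 <- solve_prism_compression(m1, force = 2, tol = 1e-12)
  expect_equal(s2$u, 2 * s1$u, tolerance = 1e-8)
  m2 <- prism_model(4, 4, 6, E = 14.3)
  s3 <- solve_prism_compression(m2, force = 1, tol = 1e-12)
  expect_equal(s3$u, s1$u / 2, tolerance = 1e-8)
})

test_that("any affine field is reproduced exactly on an arbitrary uniform mesh", {
  set.seed(42)
  occ <- array(runif(7 * 6 * 5) < 0.7, c(7, 6, 5))
  g <- array(0, c(14, 12, 10))
  for (d in 0:1) for (e in 0:1) for (f in 0:1)
    g[seq(1 + d, 14, 2), seq(1 + e, 12, 2), seq(1 + f, 10, 2)][occ] <- 200
  m <- build_mesh(image_volume(g, 0.018))
  A <- matrix(c(2e-4, 1e-4, 0, 5e-5, -3e-4, 8e-5, -2e-5, 6e-5, 4e-4), 3, 3)
  uaff <- (m$node_grid * m$side) %*% t(A)
  deg <- table(as.vector(m$e2n))
  boundary <- as.integer(names(deg)[deg < 8])
  dirb <- do.call(rbind, lapply(1:3, function(ax)
    data.frame(node = boundary, axis = ax, value = uaff[boundary, ax])))
  sol <- solve_fe(m, dirichlet = dirb, tol = 1e-12)
  expect_lt(max(abs(sol$u - uaff)), 1e-12)
  st <- element_strains(m, sol$u)
  sym <- (A + t(A)) / 2
  expect_equal(unname(st$tensor[1, c("xx", "yy", "zz")]), diag(sym),
               tolerance = 1e-9)
})

test_that("centroid strains diagonalise as expected for canonical states", {
  m <- prism_model(2, 2, 2, E = 10)
  coords <- m$node_grid * m$side
  # uniaxial -1000 ue with free Poisson expansion at nu = 0.3
  u <- cbind(3e-4 * coords[, 1], 3e-4 * coords[, 2], -1e-3 * coords[, 3])
  st <- element_strains(m, u)
  expect_equal(unname(st$principal[1, ]), c(300, 300, -1000), tolerance = 1e-9)
  # pure shear gamma = 2000 ue -> principal +-1000 ue
  u2 <- cbind(1e-3 * coords[, 2], 1e-3 * coords[, 1], 0 * coords[, 3])
  st2 <- element_strains(m, u2)
  expect_equal(unname(st2$principal[1, ]), c(1000, 0, -1000), tolerance = 1e-9)
  # rigid translation: no strain (tolerance in strain units, not ue)
  u3 <- cbind(rep(1, nrow(coords)), rep(-2, nrow(coords)), rep(3, nrow(coords)))
  expect_lt(max(abs(element_strains(m, u3)$principal)) / 1e6, 1e-12)
})

test_that("strain summaries tighten negligibly when the solver tolerance tightens", {
  m <- prism_model(4, 4, 8, E = 10)
  m <- apply_compression(m, 5)
  s8 <- strain_summary(element_strains(m, solve_fe(m, tol = 1e-8)$u))
  s10 <- strain_summary(element_strains(m, solve_fe(m, tol = 1e-10)$u))
  expect_lt(abs(s8$mean_compressive - s10$mean_compressive) /
            s10$mean_compressive, 0.005)
  expect_lt(abs(s8$mean_tensile - s10$mean_tensile) / s10$mean_tensile, 0.005)
})

test_that("the mesh exports as a readable ASCII VTK grid", {
  m <- prism_model(2, 2, 2)
  f <- tempfile(fileext = ".vtk")
  write_mesh_vtk(m, f)
  lines <- readLines(f)
  expect_equal(lines[4], "DATASET UNSTRUCTURED_GRID")
  expect_true(any(grepl("^POINTS 27 double", lines)))
  expect_true(any(grepl("^CELLS 8 72", lines)))
  expect_true(any(grepl("modulus_GPa", lines)))
})
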