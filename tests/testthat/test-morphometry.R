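annulus_fixture <- function(vs = 0.018, length = 0.2) {
  a <- generate_phantom(phantom_spec("annulus_diaphysis", voxel_size = vs,
                                     r_outer = 1.0, r_inner = 0.5,
                                     length = length))
  a$voi <- voi_spec("cortical", 1, dim(a$bone_mask)[3] + 1)
  a
}

test_that("bone volume fraction counts bone over the VOI", {
  p <- generate_phantom(phantom_spec("plate_lattice", plate_thickness = 0.036,
                                     plate_gap = 0.108, side = 1.152))
  v <- voi_spec("trabecular", 1, dim(p$bone_mask)[3] + 1)
  expect_equal(bv_tv(p$bone_mask, v), 0.25, tolerance = 0.01)
  empty <- array(FALSE, dim(p$bone_mask))
  expect_equal(bv_tv(empty, v), 0)
  expect_equal(bv_tv(array(TRUE, dim(p$bone_mask)), v), 1)
  # restricted denominator
  reg <- array(FALSE, dim(p$bone_mask)); reg[, 1:32, ] <- TRUE
  expect_equal(bv_tv(p$bone_mask, v, reg), 0.25, tolerance = 0.01)
})

test_that("trabecular number is volume fraction over thickness", {
  expect_equal(tb_n(0.25, 0.036), 1 / 0.144)
  expect_equal(tb_n(0, 0), 0)
  expect_equal(tb_n(0.25, 0.072), tb_n(0.25, 0.036) / 2)  # doubling t and g
  expect_error(tb_n(0.2, 0))
})

test_that("mean calibrated density distinguishes BMD (VOI) from TMD (bone)", {
  map <- fit_phantom_map(50, 150)
  g <- array(30, c(8, 8, 4)); g[3:6, 3:6, ] <- 150
  vol <- image_volume(g, 0.018)
  v <- voi_spec("trabecular", 1, 5)
  bone <- array(g >= 65, dim(g))
  tmd <- mean_density(vol, bone, map)
  bmd <- mean_density(vol, v, map)
  expect_equal(tmd, 0.75)  # calibration node, exact
  expect_lt(bmd, tmd)      # marrow dilutes the VOI mean
  frac <- mean(bone)
  expect_equal(bmd, frac * 0.75 + (1 - frac) * map(30))
  expect_error(mean_density(vol, array(FALSE, dim(g)), map), "empty")
})

test_that("digitised annulus reproduces closed-form section properties within 2%", {
  a <- annulus_fixture()
  sp <- section_properties(a$bone_mask, a$voi, 0.018)
  rel <- function(x, y) abs(x - y) / y
  expect_lt(rel(sp$Ct_Ar, a$truth$Ct_Ar), 0.02)
  expect_lt(rel(sp$Tt_Ar, a$truth$Tt_Ar), 0.02)
  expect_lt(rel(sp$Ma_Ar, a$truth$Ma_Ar), 0.02)
  expect_lt(rel(sp$Ps_Pm, a$truth$Ps_Pm), 0.02)
  expect_lt(rel(sp$Ec_Pm, a$truth$Ec_Pm), 0.02)
  expect_lt(rel(sp$I_p, a$truth$I_p), 0.02)
  expect_lte(sp$Ecc, 0.05)
  expect_lt(rel(sp$c_max, 1.0), 0.02)
  expect_lt(rel(sp$b_ap, 2.0), 0.02)
  expect_lt(rel(sp$Ct_Th, 0.5), 0.05)  # ring width, one-voxel-scale bias
  # area closure at 18 um
  expect_lt(abs(sp$Tt_Ar - sp$Ct_Ar - sp$Ma_Ar) / sp$Tt_Ar, 0.01)
})

test_that("polar moment is exactly the sum of the principal moments", {
  set.seed(31)
  for (i in 1:5) {
    m <- array(FALSE, c(40, 40, 1))
    m[sample(40, 20), sample(40, 20), 1] <- TRUE
    m[10:30, 15:25, 1] <- TRUE  # guarantee mass
    sp <- section_properties(m, voi_spec("cortical", 1, 2), 0.018)
    expect_identical(sp$I_p, sp$I_min + sp$I_max)
    expect_true(sp$Ecc >= 0 && sp$Ecc < 1)
  }
})

test_that("a solid square section matches its closed forms", {
  sq <- array(FALSE, c(80, 80, 2)); sq[21:60, 21:60, ] <- TRUE
  sp <- section_properties(sq, voi_spec("cortical", 1, 3), 0.018)
  a <- 40 * 0.018
  expect_equal(sp$I_min, a^4 / 12, tolerance = 1e-9)
  expect_equal(sp$I_max, a^4 / 12, tolerance = 1e-9)
  expect_equal(sp$I_p, a^4 / 6, tolerance = 1e-9)
  expect_equal(sp$Ma_Ar, 0)
  expect_equal(sp$Ct_Ar, a^2, tolerance = 1e-9)
})

test_that("section properties are invariant under a quarter rotation", {
  # an eccentric section: ellipse-ish blob
  n <- 90
  xs <- (1:n) - 30; ys <- (1:n) - 45
  m <- array(outer(xs^2 / 28^2, ys^2 / 14^2, "+") <= 1, c(n, n, 1))
  v <- voi_spec("cortical", 1, 2)
  sp <- section_properties(m, v, 0.018)
  rot <- array(t(m[n:1, , 1]), c(n, n, 1))  # 90-degree rotation
  spr <- section_properties(rot, v, 0.018)
  for (nm in c("Tt_Ar", "Ct_Ar", "Ps_Pm", "I_min", "I_max", "I_p", "Ecc"))
    expect_equal(spr[[nm]], sp[[nm]], tolerance = 0.01)
  expect_gt(sp$Ecc, 0.5)  # genuinely eccentric fixture
})

test_that("broken cortical rings are excluded; all-broken fails", {
  ring <- annulus_fixture(length = 0.09)  # 5 slices
  m <- ring$bone_mask
  m[, 56:60, 3] <- FALSE  # thin cut: an open ring, not a solid section
  expect_warning(sp <- section_properties(m, ring$voi, 0.018), "excluded")
  expect_false(3 %in% sp$per_slice$z)
  expect_equal(nrow(sp$per_slice), 4)
  allcut <- ring$bone_mask
  allcut[, 56:60, ] <- FALSE
  expect_error(suppressWarnings(
    section_properties(allcut, ring$voi, 0.018)), "no slice")
})

test_that("trabecular metrics assemble the full parameter set", {
  p <- generate_phantom(phantom_spec("plate_lattice", plate_thickness = 0.09,
                                     plate_gap = 0.126, side = 1.296,
                                     grayscale_bone = 150))
  v <- voi_spec("trabecular", 1, dim(p$bone_mask)[3] + 1)
  map <- fit_phantom_map(50, 150)
  tm <- trabecular_metrics(p$volume, p$bone_mask, v, map)
  expect_equal(tm$BV_TV, p$truth$BV_TV, tolerance = 0.01)
  expect_equal(tm$Tb_Th, 0.09, tolerance = 1e-9)
  expect_equal(tm$Tb_N, tm$BV_TV / tm$Tb_Th)
  expect_equal(tm$BMD, tm$BV_TV * 0.75 + (1 - tm$BV_TV) * map(30),
               tolerance = 1e-6)
  tab <- metrics_to_table(tm, "spec1", 11)
  expect_setequal(tab$parameter, c("BMD", "BV_TV", "Tb_Th", "Tb_Sp", "Tb_N"))
})
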