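test_that("geometric phantoms carry exact closed-form ground truth", {
  # parallel plates: 2-voxel plates, 6-voxel gaps
  p <- generate_phantom(phantom_spec("plate_lattice", plate_thickness = 0.036,
                                     plate_gap = 0.108, side = 1.152))
  expect_equal(p$truth$BV_TV, 0.25)
  expect_equal(p$truth$Tb_N, 1 / 0.144)  # 6.944 per mm
  expect_equal(mean(p$bone_mask), 0.25)  # aligned lattice digitises exactly

  a <- generate_phantom(phantom_spec("annulus_diaphysis", r_outer = 1.0,
                                     r_inner = 0.5, length = 0.1))
  expect_equal(a$truth$Ct_Ar, pi * (1 - 0.25))          # 2.3562 mm^2
  expect_equal(a$truth$I_p, pi / 2 * (1 - 0.5^4))       # 1.4726 mm^4
  expect_equal(a$truth$I_min + a$truth$I_max, a$truth$I_p)

  u <- generate_phantom(phantom_spec("uniform_block", noise_sd = 0))
  expect_true(all(u$volume$data[u$bone_mask] == 160))
  expect_true(all(u$volume$data[!u$bone_mask] == 30))
})

test_that("phantom generation is seeded, truncated to 8 bits, and validated", {
  s <- phantom_spec("uniform_block", noise_sd = 20, seed = 11, side = 0.36)
  v1 <- generate_phantom(s)$volume$data
  v2 <- generate_phantom(s)$volume$data
  expect_identical(v1, v2)
  v3 <- generate_phantom(phantom_spec("uniform_block", noise_sd = 20,
                                      seed = 12, side = 0.36))$volume$data
  expect_false(identical(v1, v3))
  expect_true(all(v1 >= 0 & v1 <= 255))
  expect_error(phantom_spec("annulus_diaphysis", r_inner = 1, r_outer = 0.5),
               "inner radius")
  expect_error(generate_phantom(phantom_spec("uniform_block", side = 20)),
               "512")
})

test_that("digitised morphometry converges to phantom ground truth with resolution", {
  errs <- sapply(c(0.036, 0.018), function(vs) {
    a <- generate_phantom(phantom_spec("annulus_diaphysis", voxel_size = vs,
                                       length = 0.2))
    v <- voi_spec("cortical", 1, dim(a$bone_mask)[3] + 1)
    sp <- section_properties(a$bone_mask, v, vs)
    c(abs(sp$Ct_Ar - a$truth$Ct_Ar), abs(sp$Tt_Ar - a$truth$Tt_Ar),
      abs(sp$I_p - a$truth$I_p))
  })
  expect_true(all(errs[, 2] < errs[, 1]))  # finer voxels, smaller error

  th_err <- sapply(c(0.024, 0.012), function(vs) {
    p <- generate_phantom(phantom_spec("plate_lattice", voxel_size = vs,
                                       plate_thickness = 0.05,
                                       plate_gap = 0.1, side = 1.05))
    abs(local_thickness(p$bone_mask, vs)$mean - p$truth$Tb_Th)
  })
  expect_lt(th_err[2], th_err[1])
})

test_that("the scaled tibia phantom has consistent landmarks, labels and inserts", {
  spec <- tibia_spec(voxel_size = 0.036, noise_sd = 6, seed = 3)
  tib <- generate_full_tibia(spec)
  vs <- spec$voxel_size

  bone_z <- which(apply(tib$labels$bone, 3, any))
  expect_lt(abs(diff(range(bone_z)) * vs - tib$landmarks$total_length_L), 2 * vs)

  # insert mean grayscale recovers the set value within the sampling error
  for (lab in c("insert_low", "insert_high")) {
    target <- if (lab == "insert_low") spec$grayscale_insert_low
              else spec$grayscale_insert_high
    m <- tib$labels[[lab]]
    expect_lt(abs(mean(tib$volume$data[m]) - target),
              4 * spec$noise_sd / sqrt(sum(m)))
  }

  # the located trabecular VOI lies inside the generated compartment
  tvoi <- locate_trabecular_voi(tib$volume)
  sl <- voi_slices(tvoi)
  expect_true(all(apply(tib$labels$trabecular_compartment[, , sl], 3, any)))
  # and all lattice bone in those slices is inside the compartment
  expect_true(all(tib$labels$trabecular[, , sl] ==
                  (tib$labels$trabecular[, , sl] &
                   tib$labels$trabecular_compartment[, , sl])))
})

test_that("synthetic bending curves follow the bilinear-plus-fracture template", {
  cv <- generate_curve(curve_spec())      # k = 250, Fy = 100, Fult = 150
  expect_equal(as.numeric(stiffness(cv)), 250, tolerance = 1e-9)
  y <- yield_point(cv, stiffness(cv))
  w <- works_and_postyield(cv, list(F_y = 100, d_y = 0.4),
                           ultimate_and_failure(cv))
  expect_equal(w$W_y, 0.5 * 100 * (100 / 250), tolerance = 1e-3) # 20 mJ
  expect_identical(generate_curve(curve_spec(noise_sd = 1, seed = 5)),
                   generate_curve(curve_spec(noise_sd = 1, seed = 5)))
  expect_error(curve_spec(yield_force = 200, ultimate_force = 150))
  expect_error(curve_spec(fracture_drop_fraction = 0))
})

test_that("the study generator honours design, seed and CLT bounds", {
  des <- study_design(correlation = 0, seed = 42)
  d <- generate_study(des)
  expect_equal(nrow(d), sum(des$groups$n_animals) * length(des$timepoints))
  expect_true(all(table(d$animal, d$week) == 1))
  N <- nrow(d)
  expect_lt(abs(mean(d$value) - 0.25), 4 * 0.03 / sqrt(N))
  expect_identical(generate_study(des), generate_study(des))
  expect_error(study_design(groups = data.frame(name = "a", n_animals = 1)),
               "n_animals >= 2")
  expect_silent(study_design(groups = data.frame(name = c("a", "b"),
                                                 n_animals = c(2, 2))))
  expect_error(study_design(correlation = 1), "correlation")
})

test_that("effects shift the targeted group at the targeted timepoint", {
  ef <- data.frame(group = "high", week = 22, parameter = "BV_TV", effect_sd = 3)
  d <- generate_study(study_design(effects = ef, correlation = 0, seed = 9))
  hit <- d$value[d$group == "high" & d$week == 22]
  rest <- d$value[!(d$group == "high" & d$week == 22)]
  expect_gt(mean(hit) - mean(rest), 1.5 * 0.03)
})
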