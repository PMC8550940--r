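test_that("all constructed dimensions are recovered from the noise-free phantom", {
  ph <- wildtype_phantom()
  m <- measure_npc(ph)
  vx_nm <- ph$voxel_size / 10
  expect_lt(abs(m$pore_diameter_nm - 105), vx_nm)
  expect_lt(abs(m$channel_diameter_nm - 57), vx_nm)
  expect_lt(abs(m$ir_cr_nm - 37), vx_nm)
  expect_lt(abs(m$ir_nr_nm - 29), vx_nm)
  expect_lt(abs(m$height_nm - 66), vx_nm)
  expect_lt(abs(m$angle_cyto_deg - 42), 2)
  expect_lt(abs(m$angle_nucleo_deg - 28), 2)
  # additivity is exact by construction
  ax <- measure_axial_geometry(ph)
  expect_identical(ax$height_nm, ax$ir_cr_nm + ax$ir_nr_nm)
})

test_that("the constricted preset recovers the narrower channel", {
  ph <- cached("constricted112",
               build_phantom(npc_preset("constricted"), 112, 13.6))
  cd <- measure_channel_diameter(ph)
  expect_lt(abs(as.numeric(cd) - 43), 1.36)
})

test_that("an elliptical pore reports the mean of the two orthogonal axes", {
  n <- 112; vx <- 13.6
  xs <- axis_coords(n, vx); ys <- axis_coords(n, vx); zs <- axis_coords(n, vx)
  ax <- 500; by <- 550                      # semi-axes 50 / 55 nm
  u <- sqrt(outer((xs / ax)^2, (ys / by)^2, "+"))
  sigma_u <- 30 / ((ax + by) / 2)
  ring2d <- exp(-(u - 1)^2 / (2 * sigma_u^2))
  gz <- exp(-zs^2 / (2 * 30^2))
  v <- density_volume(
    array(outer(ring2d, gz), c(n, n, n)), vx)
  pd <- measure_pore_diameter(v, angles = c(0, 90))
  expect_lt(abs(as.numeric(pd) - 105), 1.36)
  per <- attr(pd, "per_direction")
  expect_lt(abs(per[["a0"]] - 100), 1.36)
  expect_lt(abs(per[["a90"]] - 110), 1.36)
})

test_that("diameter measurements are invariant to rotations about z", {
  ph <- wildtype_phantom()
  r30 <- rotate_volume(ph, c(30, 0, 0))
  expect_lt(abs(as.numeric(measure_pore_diameter(r30)) -
                as.numeric(measure_pore_diameter(ph))), 1.36)
  expect_lt(abs(as.numeric(measure_channel_diameter(r30)) -
                as.numeric(measure_channel_diameter(ph))), 1.36)
})

test_that("measured channel diameter increases monotonically with the built one", {
  prev <- -Inf
  for (cd in seq(43, 57, length.out = 5)) {
    ph <- build_phantom(npc_preset("wildtype", channel_diameter = cd,
                                   ir_outer_diameter = cd + 36),
                        112, 13.6)
    got <- as.numeric(measure_channel_diameter(ph))
    expect_gt(got, prev)
    expect_lt(abs(got - cd), 1.36)
    prev <- got
  }
})

test_that("empty volumes raise a measurement error", {
  empty <- density_volume(array(0, rep(48, 3)), 13.6)
  expect_error(measure_pore_diameter(empty), "no membrane")
})

test_that("a flat membrane measures an angle near zero", {
  n <- 96; vx <- 13.6
  xs <- axis_coords(n, vx); zs <- axis_coords(n, vx)
  r <- sqrt(outer(outer(xs^2, xs^2, "+"), 0 * zs, "+"))
  zz <- array(rep(zs, each = n * n), rep(n, 3))
  sheet <- exp(-zz^2 / (2 * 30^2)) * (r > 300) *
    porescope:::cosine_ramp(r - (n / 2 - 3) * vx, 2 * vx)
  v <- density_volume(array(sheet, rep(n, 3)), vx)
  an <- measure_membrane_angles(v, pore_diameter_nm = 60)
  expect_lt(abs(an[["cyto"]]), 3)
  expect_lt(abs(an[["nucleo"]]), 3)
})

test_that("channel cylinder volume follows the closed form and the printed ratios", {
  expect_equal(channel_cylinder_volume(57, 20), pi * 28.5^2 * 20,
               tolerance = 1e-12)
  expect_equal(channel_cylinder_volume(0), 0)
  expect_error(channel_cylinder_volume(-3), ">= 0")
  expect_equal(percent_increase(43, 57), 100 * (57 / 43 - 1),
               tolerance = 1e-12)
  expect_error(percent_increase(0, 5), "> 0")
})

test_that("ring presence calls match the class phantoms", {
  for (cls in c("class1", "class3")) {
    params <- npc_preset(cls)
    ph <- build_phantom(params, 96, 13.6)
    pres <- ring_presence(ph, ring_shell_specs(params))
    expect_setequal(pres, params$present_rings)
  }
})

test_that("class-2 presence calls are stable across seeded noisy averages", {
  params <- small_params(present_rings = c("IR", "NR"))
  ph <- build_phantom(params, 48, 13.6)
  shells <- ring_shell_specs(small_params(), width_sigma = 1)
  hits <- 0
  for (seed in 1:8) {
    sim <- sim_params(n_particles = 16, snr = 0.5, pose_jitter = 1,
                      seed = seed)
    out <- simulate_particles(ph, sim, 40)
    avg <- average_particles(out$particles, out$table, out$wedge)
    v <- apply_symmetry(avg$merged, 8)
    pres <- ring_presence(v, shells, threshold_sigma = 5)
    if (setequal(pres, c("IR", "NR"))) hits <- hits + 1
  }
  expect_gte(hits, 7)
})

test_that("summaries apportion class percentages to a 100% total", {
  rep1 <- summarize_measurements(rep(1:3, c(27, 53, 83)),
                                 list(diam = c(100, 105, 110)))
  expect_identical(rep1$classes$percent, c(17L, 32L, 51L))
  expect_equal(sum(rep1$classes$percent), 100)
  expect_equal(rep1$measurements$mean, 105)
  single <- summarize_measurements(2L)
  expect_identical(single$classes$percent, 100L)
  none <- summarize_measurements(integer(0))
  expect_equal(nrow(none$classes), 0)
})
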