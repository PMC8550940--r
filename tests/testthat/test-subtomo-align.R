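test_that("wedge masks cover the stated angular fraction and are Friedel symmetric", {
  wm <- wedge_mask(-52, 68, 64)
  expect_lt(abs(wedge_coverage(wm) - 120 / 180), 0.01)
  wide <- wedge_mask(-89.9, 89.9, 32)
  expect_gt(wedge_coverage(wide), 0.95)   # voxelized boundary
  w <- wm$w[2:64, 2:64, 2:64]              # interior: every -k has a +k
  expect_identical(w, w[63:1, 63:1, 63:1])
  expect_error(wedge_mask(60, 40, 32), "tilt")
})

test_that("constrained CC scores self-correlation and recovers circular shifts", {
  set.seed(1)
  a <- density_volume(array(rnorm(32^3), rep(32, 3)), 1)
  r <- constrained_cc(a, a, max_shift = 0)
  expect_equal(r$score, 1, tolerance = 1e-6)
  b <- density_volume(circ_shift_array(a$data, c(3, 0, 0)), 1)
  r2 <- constrained_cc(a, b, max_shift = 5)
  expect_equal(r2$shift, c(3, 0, 0), tolerance = 1e-6)
  expect_equal(r2$score, 1, tolerance = 1e-6)
})

test_that("constrained CC of independent noise stays inside the null bound", {
  set.seed(42)
  for (i in 1:3) {
    a <- density_volume(array(rnorm(48^3), rep(48, 3)), 1)
    b <- density_volume(array(rnorm(48^3), rep(48, 3)), 1)
    wm <- wedge_mask(-52, 68, 48)
    r <- constrained_cc(a, b, wedge_a = wm, wedge_b = wm, max_shift = 0)
    n_overlap <- sum(wm$w >= 0.5)
    expect_lt(abs(r$score), 3 / sqrt(n_overlap))
  }
})

test_that("constrained CC equals plain correlation under full wedges", {
  set.seed(8)
  for (i in 1:5) {
    a <- density_volume(array(rnorm(24^3), rep(24, 3)), 1)
    b <- density_volume(array(rnorm(24^3), rep(24, 3)), 1)
    r <- constrained_cc(a, b, max_shift = 0)
    expect_lt(abs(r$score - cor(as.vector(a$data), as.vector(b$data))), 1e-6)
  }
})

test_that("degenerate overlap raises an error", {
  z <- density_volume(array(0, rep(16, 3)), 1)
  a <- density_volume(array(rnorm(16^3), rep(16, 3)), 1)
  expect_error(constrained_cc(a, z), "degenerate")
})

test_that("alignment recovers a 20-degree in-plane rotation to the refined step", {
  ref <- blob_volume(32)
  part <- rotate_volume(ref, c(0, 0, 20))
  wfull <- wedge_mask(-89, 89, 32)
  cfg <- align_config(angular_step = 5, max_tilt = 5, symmetry = 1,
                      binnings = 1, n_iter = 1, max_shift = 2)
  res <- align_particle(part, ref, wfull, cfg)
  expect_lt(porescope:::rotation_distance(euler_matrix(res$pose),
                                          euler_matrix(c(0, 0, 20))), 1.3)
  expect_gt(res$cc, 0.99)
  # identity particle: identity pose, score 1
  res0 <- align_particle(ref, ref, wfull, cfg)
  expect_lt(porescope:::rotation_distance(euler_matrix(res0$pose), diag(3)),
            1e-6)
  expect_equal(res0$cc, 1, tolerance = 1e-6)
})

test_that("alignment is exhaustive-search consistent on a coarse grid", {
  ref <- blob_volume(24)
  part <- rotate_volume(ref, c(40, 14, -25))
  wm <- wedge_mask(-52, 68, 24)
  pw <- density_volume(porescope:::isfft(porescope:::sfft(part$data) * wm$w),
                       ref$voxel_size)
  cfg <- align_config(angular_step = 15, max_tilt = 30, symmetry = 1,
                      binnings = 1, n_iter = 1, max_shift = 1)
  res <- align_particle(pw, ref, wm, cfg)
  grid <- porescope:::angular_grid(15, 30, 1)
  node_scores <- apply(grid, 1, function(e) {
    constrained_cc(rotate_volume(ref, e), pw, wedge_b = wm,
                   max_shift = 1)$score
  })
  expect_gte(res$cc, max(node_scores) - 1e-3)
})

test_that("averaging compensates wedges and handles single particles", {
  ph <- small_phantom()
  wm <- wedge_mask(-52, 68, 48)
  wf <- porescope:::apply_wedge(ph, wm)
  tab <- particle_table(c("a", "b"), half_set = c("A", "B"))
  avg <- average_particles(list(wf, wf), tab, wm)
  # agreement up to Friedel bookkeeping on the unpaired -n/2 planes
  expect_lt(max(abs(avg$merged$data - wf$data)), 1e-4 * max(abs(wf$data)))
  # single particle: merged equals that particle on its own wedge region
  tab1 <- particle_table("a", half_set = "A")
  expect_warning(avg1 <- average_particles(list(wf), tab1, wm), "half set")
  expect_lt(max(abs(avg1$merged$data - wf$data)), 1e-4 * max(abs(wf$data)))
  S <- porescope:::sfft(avg1$merged$data)
  expect_lt(max(Mod(S[wm$w < 0.5])), 1e-4 * max(Mod(S)))
  expect_error(average_particles(list(), particle_table(character(0))[0, ],
                                 wm), "particle")
})

test_that("complementary wedge coverage leaves no systematic amplitude loss", {
  v <- smooth_noise_volume(32, 3, voxel = 10, b_soft = 3000)
  wm <- wedge_mask(-45, 45, 32)            # 90-degree coverage
  p1 <- porescope:::apply_wedge(v, wm)
  r90 <- rotate_volume(v, c(90, 0, 0))
  p2 <- porescope:::apply_wedge(r90, wm)
  tab <- particle_table(c("a", "b"), rot = c(0, 90),
                        half_set = c("A", "B"))
  avg <- average_particles(list(p1, p2), tab, wm)
  S <- porescope:::sfft(avg$merged$data)
  pw <- Re(S)^2 + Im(S)^2
  W1 <- wm$w >= 0.5
  W2 <- porescope:::wedge_array_rotated(wm, euler_matrix(c(90, 0, 0))) >= 0.5
  union <- W1 | W2
  ratio <- mean(pw[W1 & union]) / mean(pw[!W1 & union])
  expect_gt(ratio, 0.8); expect_lt(ratio, 1.25)
})

test_that("symmetrization is idempotent, order-1 safe, and kills forbidden harmonics", {
  # idempotence on an analytically band-limited map (Gaussian mixture with
  # tails below machine noise at the box edge, so rotation is closed)
  n <- 48; vx <- 10
  xs <- axis_coords(n, vx)
  gauss3 <- function(cx, cy, cz, s) {
    array(outer(outer(exp(-(xs - cx)^2 / (2 * s^2)),
                      exp(-(xs - cy)^2 / (2 * s^2))),
                exp(-(xs - cz)^2 / (2 * s^2))), rep(n, 3))
  }
  v <- density_volume(gauss3(45, 25, -15, 40) + 0.7 * gauss3(-30, 40, 25, 40) +
                      0.5 * gauss3(0, -50, 10, 40), vx)
  expect_identical(apply_symmetry(v, 1)$data, v$data)
  s1 <- apply_symmetry(v, 8)
  s2 <- apply_symmetry(s1, 8)
  expect_lt(max(abs(s2$data - s1$data)) / max(abs(s1$data)), 1e-5)
  # commutes with rotation by the symmetry angle
  r45 <- rotate_volume(s1, c(45, 0, 0))
  expect_lt(max(abs(r45$data - s1$data)) / max(abs(s1$data)), 1e-4)
  expect_error(apply_symmetry(v, 0), "order")
  # circular harmonics on an equatorial ring of a random (windowed) map
  vn <- smooth_noise_volume(48, 12, voxel = 10, b_soft = 25000, offset = 2)
  win <- make_mask(mask_spec("soft_sphere", radius = 190, soft_edge = 3),
                   48, 10)
  vn$data <- vn$data * win$data
  sn <- apply_symmetry(vn, 8)
  harm <- function(vol, radius = 12, n_ang = 256) {
    ctr <- dim(vol$data) %/% 2 + 1
    ang <- 2 * pi * (0:(n_ang - 1)) / n_ang
    coords <- cbind(ctr[1] + radius * cos(ang), ctr[2] + radius * sin(ang),
                    ctr[3])
    Mod(fft(porescope:::sample_trilinear(vol$data, coords)))^2
  }
  h0 <- harm(vn); h1 <- harm(sn)
  expect_lt(h1[4], 0.01 * h1[1])                    # m = 3 suppressed
  expect_gt(h1[9] / h0[9], 0.5)                     # m = 8 preserved
  expect_lt(h1[9] / h0[9], 1.5)
})

test_that("iterative alignment converges to the wedge-compensated phantom", {
  ph <- small_phantom()
  sim <- sim_params(n_particles = 8, snr = 1e9, pose_jitter = 1, wobble = 10,
                    seed = 6)
  out <- simulate_particles(ph, sim, 40)
  oracle <- average_particles(out$particles, out$table, out$wedge)
  oracle_sym <- apply_symmetry(oracle$merged, 8)
  init <- out$table
  init$rot <- 0; init$tilt <- 0; init$psi <- 0
  init$x <- 0; init$y <- 0; init$z <- 0
  cfg <- align_config(angular_step = 10, max_tilt = 15, symmetry = 8,
                      binnings = 1, n_iter = 2, max_shift = 2)
  res <- iterative_align(out$particles, init, cfg)
  expect_gt(vol_cor(res$merged, oracle_sym), 0.99)
  expect_true(all(diff(res$log$mean_cc) > -0.01))
})

test_that("zero iterations return the initial reference and runs are deterministic", {
  ph <- small_phantom()
  sim <- sim_params(n_particles = 4, snr = 1, seed = 5)
  out <- simulate_particles(ph, sim, 40)
  cfg0 <- align_config(binnings = 1, n_iter = 0, symmetry = 8)
  r0 <- iterative_align(out$particles, out$table, cfg0)
  manual <- apply_symmetry(average_particles(out$particles, out$table,
                                             out$wedge)$merged, 8)
  expect_lt(max(abs(r0$merged$data - manual$data)), 1e-10 * max(manual$data))
  cfg <- align_config(angular_step = 15, max_tilt = 15, symmetry = 8,
                      binnings = 1, n_iter = 1, max_shift = 2)
  init <- out$table; init$rot <- 0; init$tilt <- 0; init$psi <- 0
  init$x <- 0; init$y <- 0; init$z <- 0
  ra <- iterative_align(out$particles, init, cfg)
  rb <- iterative_align(out$particles, init, cfg)
  expect_identical(ra$merged$data, rb$merged$data)
  expect_identical(ra$table, rb$table)
})
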