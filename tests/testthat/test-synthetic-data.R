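test_that("the default phantom is C8 symmetric about z", {
  ph <- wildtype_phantom()
  r45 <- rotate_volume(ph, c(45, 0, 0))
  expect_lt(max(abs(ph$data - r45$data)) / max(ph$data), 0.02)
})

test_that("omitted rings leave no density in their shells", {
  params <- npc_preset("class3")          # IR only
  ph <- build_phantom(params, 96, 13.6)
  shells <- ring_shell_specs(params)
  m_ir <- make_mask(shells$IR, dim(ph$data), ph$voxel_size)
  ir_mean <- mean(ph$data[m_ir$data >= 0.5])
  expect_gt(ir_mean, 0.1)
  for (ring in c("CR", "NR")) {
    m <- make_mask(shells[[ring]], dim(ph$data), ph$voxel_size)
    # empty up to Gaussian tails of the rendered IR
    expect_lt(mean(ph$data[m$data >= 0.5]), 5e-3 * ir_mean)
  }
})

test_that("a symmetric parameter set gives a midplane mirror-symmetric phantom", {
  params <- phantom_params(membrane_pore_diameter = 40, channel_diameter = 22,
                           ir_outer_diameter = 34, cr_distal_offset = 12,
                           nr_distal_offset = 12, angle_cyto = 35,
                           angle_nucleo = 35, membrane_thickness = 6,
                           ring_thickness = 8, present_rings = "IR")
  ph <- build_phantom(params, 48, 13.6)
  n <- dim(ph$data)[3]
  flipped <- ph$data[, , n:2]              # indices symmetric about centre
  expect_lt(max(abs(ph$data[, , 2:n] - flipped)), 1e-10 * max(ph$data))
})

test_that("phantom point models count, land on density, and reject empty ring sets", {
  params <- small_params(present_rings = "IR")
  pm <- phantom_point_model(params, points_per_subunit = 3)
  expect_equal(nrow(pm), 8 * 3)
  ph <- small_phantom()
  ctr <- dim(ph$data) %/% 2 + 1
  coords <- sweep(as.matrix(pm[, 1:3]) / ph$voxel_size, 2, ctr, "+")
  vals <- porescope:::sample_trilinear(ph$data, coords)
  expect_true(all(vals > 0.01 * max(ph$data)))
  pm3 <- phantom_point_model(small_params(), 1)
  expect_equal(nrow(pm3), 3 * 8)
  expect_error(phantom_point_model(small_params(present_rings = character(0))),
               "empty model")
})

test_that("noise-free identity-pose particles equal the wedge-filtered phantom", {
  ph <- small_phantom()
  sim <- sim_params(n_particles = 1, snr = 1e12, pose_jitter = 0,
                    random_azimuth = FALSE, seed = 2)
  out <- simulate_particles(ph, sim, pore_diameter_nm = 40)
  wf <- porescope:::apply_wedge(ph, out$wedge)
  expect_lt(max(abs(out$particles[[1]]$data - wf$data)) / max(abs(wf$data)),
            1e-6)
})

test_that("simulation is reproducible from its seed and assigns half sets A,B,A,B", {
  ph <- small_phantom()
  sim <- sim_params(n_particles = 6, snr = 1, seed = 9)
  out1 <- simulate_particles(ph, sim, 40)
  out2 <- simulate_particles(ph, sim, 40)
  expect_identical(lapply(out1$particles, `[[`, "data"),
                   lapply(out2$particles, `[[`, "data"))
  expect_identical(out1$table, out2$table)
  expect_identical(out1$table$half_set, rep(c("A", "B"), 3))
  out3 <- simulate_particles(ph, sim_params(n_particles = 6, snr = 1,
                                            seed = 10), 40)
  expect_false(identical(out1$particles[[1]]$data, out3$particles[[1]]$data))
})

test_that("spectral power in vs out of the wedge support matches the stated SNR", {
  ph <- small_phantom()
  n_p <- 8
  sim_n <- sim_params(n_particles = n_p, snr = 0.5, seed = 21)
  sim_0 <- sim_params(n_particles = n_p, snr = 1e12, seed = 21)
  noisy <- simulate_particles(ph, sim_n, 40)
  clean <- simulate_particles(ph, sim_0, 40)
  W <- noisy$wedge$w >= 0.5
  ratios <- expected <- numeric(n_p)
  for (i in seq_len(n_p)) {
    S <- porescope:::sfft(noisy$particles[[i]]$data)
    pw <- Re(S)^2 + Im(S)^2
    ratios[i] <- mean(pw[W]) / mean(pw[!W])
    Ssig <- porescope:::sfft(clean$particles[[i]]$data)
    pw_sig <- Re(Ssig)^2 + Im(Ssig)^2
    noise_var <- stats::var(as.vector(noisy$particles[[i]]$data -
                                      clean$particles[[i]]$data))
    noise_pw <- noise_var * length(pw)      # flat noise power per voxel
    expected[i] <- (mean(pw_sig[W]) + noise_pw) / noise_pw
  }
  expect_lt(abs(mean(ratios) / mean(expected) - 1), 0.10)
})

test_that("recovery closure: identity-pose particles average back to the wedge-filtered phantom", {
  ph <- small_phantom()
  sim <- sim_params(n_particles = 4, snr = 1e12, pose_jitter = 0,
                    random_azimuth = FALSE, seed = 3)
  out <- simulate_particles(ph, sim, 40)
  avg <- average_particles(out$particles, out$table, out$wedge)
  wf <- porescope:::apply_wedge(ph, out$wedge)
  expect_gt(vol_cor(avg$merged, wf), 0.999)
})

test_that("simulation parameter validation catches bad SNR and tilt ranges", {
  expect_error(sim_params(snr = 0), "snr")
  expect_error(sim_params(tilt_min = 50, tilt_max = 40), "tilt")
  expect_error(sim_params(tilt_min = -95, tilt_max = 60), "tilt")
})
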