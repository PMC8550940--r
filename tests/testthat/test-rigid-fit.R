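test_that("simulated maps conserve mass and scale with resolution", {
  m1 <- point_model(matrix(0, 1, 3))
  v <- simulate_map_from_model(m1, resolution = 20, shape = 32,
                               voxel_size = 4)
  expect_equal(sum(v$data), 1, tolerance = 0.01)
  ctr <- which(v$data == max(v$data), arr.ind = TRUE)
  expect_equal(as.vector(ctr), rep(17, 3))
  # mirrored points give a mirror-symmetric map
  m2 <- point_model(rbind(c(20, 12, -8), c(-20, -12, 8)))
  v2 <- simulate_map_from_model(m2, 20, 32, 4)
  n <- 32
  expect_lt(max(abs(v2$data[2:n, 2:n, 2:n] - v2$data[n:2, n:2, n:2])), 1e-12)
  # doubling the resolution drops the peak 8-fold
  v20 <- simulate_map_from_model(m1, 20, 48, 2)
  v40 <- simulate_map_from_model(m1, 40, 48, 2)
  expect_equal(max(v20$data) / max(v40$data), 8, tolerance = 0.16)
  expect_error(simulate_map_from_model(m1, 4, 32, 4), "resolution")
})

test_that("CAM scores extremes, nulls, and intensity-affine invariance", {
  set.seed(6)
  model <- point_model(matrix(runif(30, -40, 40), 10, 3))
  mm <- simulate_map_from_model(model, 25, 32, 4)
  expect_equal(cam_score(mm, mm), 1, tolerance = 1e-10)
  neg <- density_volume(-mm$data, 4)
  expect_equal(cam_score(neg, mm), -1, tolerance = 1e-10)
  set.seed(7)
  noise <- density_volume(array(rnorm(32^3), rep(32, 3)), 4)
  region_n <- sum(mm$data > 1e-3 * max(mm$data))
  expect_lt(abs(cam_score(noise, mm)), 3 / sqrt(region_n))
  aff <- density_volume(3.7 * noise$data + 11, 4)
  expect_lt(abs(cam_score(aff, mm) - cam_score(noise, mm)), 1e-10)
  tiny <- density_volume(array(0, rep(32, 3)), 4)
  tiny$data[16, 16, 16] <- 1
  expect_error(cam_score(noise, tiny), "degenerate")
})

test_that("overlap scores full, zero, and half-in constructions", {
  a <- point_model(matrix(c(-30, 0, 0), 1, 3))
  b <- point_model(matrix(c(30, 0, 0), 1, 3))
  ab <- point_model(rbind(c(-30, 0, 0), c(30, 0, 0)))
  map_a <- simulate_map_from_model(a, 20, 48, 4)
  map_ab <- simulate_map_from_model(ab, 20, 48, 4)
  expect_equal(overlap_score(map_ab, map_ab, target_contour = 1e-6), 1,
               tolerance = 1e-6)
  far <- point_model(matrix(c(0, 60, 0), 1, 3))
  map_far <- simulate_map_from_model(far, 20, 48, 4)
  expect_lt(overlap_score(map_a, map_far, target_contour = 1e-4), 0.02)
  # two equal blobs, only one inside the target support
  expect_equal(overlap_score(map_a, map_ab, target_contour = 1e-4), 0.5,
               tolerance = 0.02)
})

test_that("local optimization is a fixed point at the optimum and re-converges", {
  set.seed(9)
  model <- point_model(matrix(runif(36, -50, 50), 12, 3))
  target <- simulate_map_from_model(model, 25, 40, 4)
  opt <- local_optimize(target, model, rigid_transform(), "cam")
  expect_gte(opt$score, cam_score(target, target) - 1e-9)
  expect_lt(sqrt(sum(opt$transform$translation^2)), 2)
  # displaced by 3 voxels: converges to within half a voxel
  init <- rigid_transform(translation = c(12, 0, 0))
  opt2 <- local_optimize(target, model, init, "cam")
  expect_lt(sqrt(sum(opt2$transform$translation^2)), 0.5 * 4)
  expect_gt(opt2$cam, 0.98)
})

test_that("global self-fit recovers the identity as the top cluster", {
  set.seed(10)
  model <- point_model(matrix(runif(36, -50, 50), 12, 3))
  target <- simulate_map_from_model(model, 25, 40, 4)
  fits <- global_fit(target, model, n_placements = 150, seed = 7)
  top <- fits[1, ]
  Rtop <- euler_matrix(c(top$rot, top$tilt, top$psi))
  expect_lt(porescope:::rotation_distance(Rtop, diag(3)), 2)
  expect_lt(sqrt(top$tx^2 + top$ty^2 + top$tz^2), 4)
  expect_gt(top$cam, 0.99)
  one <- global_fit(target, model, n_placements = 1, seed = 3)
  expect_equal(nrow(one), 1)
})

test_that("an exactly C2-symmetric model yields two equal top clusters", {
  base <- matrix(c(30, 10, 5, 10, -25, 18, -8, 14, 30), 3, 3, byrow = TRUE)
  c2 <- rbind(base, base %*% t(euler_matrix(c(180, 0, 0))))
  model <- point_model(c2)
  target <- simulate_map_from_model(model, 25, 40, 4)
  fits <- global_fit(target, model, n_placements = 200, seed = 11)
  expect_gte(nrow(fits), 2)
  expect_lt(abs(fits$cam[1] - fits$cam[2]), 1e-3)
  R1 <- euler_matrix(c(fits$rot[1], fits$tilt[1], fits$psi[1]))
  R2 <- euler_matrix(c(fits$rot[2], fits$tilt[2], fits$psi[2]))
  expect_gt(porescope:::rotation_distance(R1, R2), 90)
})

test_that("fit significance gives z = +/-1 for two clusters and applies BH", {
  res <- data.frame(cluster_id = 1:2, score = c(0.8, 0.3))
  out <- fit_significance(res)
  expect_equal(out$z, c(1, -1), tolerance = 1e-12)
  expect_equal(out$p, rep(2 * (1 - pnorm(1)), 2), tolerance = 1e-4)
  expect_equal(round(out$p[1], 4), 0.3173)
  expect_true(all(out$q >= out$p))
  expect_error(fit_significance(data.frame(score = c(0.5, 0.5))),
               "degenerate")
  expect_error(fit_significance(data.frame(score = 0.5)), "clusters")
})

test_that("Benjamini-Hochberg matches the brute-force step-up definition", {
  expect_equal(p.adjust(c(0.005, 0.04, 0.2), method = "BH"),
               c(0.015, 0.06, 0.2), tolerance = 1e-12)
  set.seed(12)
  for (i in 1:20) {
    p <- runif(sample(2:15, 1))
    q_pkg <- p.adjust(p, method = "BH")
    q_brute <- bh_stepup(p)
    expect_equal(q_pkg, q_brute, tolerance = 1e-12)
    expect_true(all(q_pkg >= p - 1e-15))
  }
})

test_that("density subtraction zeroes a voxelized sphere around model points", {
  set.seed(13)
  v <- density_volume(array(abs(rnorm(32^3)) + 1, rep(32, 3)), 4)
  model <- point_model(matrix(0, 1, 3))
  expect_identical(subtract_density(v, model, 0)$data, v$data)
  allgone <- subtract_density(v, model, radius = 4 * 32 * 2)
  expect_true(all(allgone$data == 0))
  r_vox <- 6
  sub <- subtract_density(v, model, radius = r_vox * 4)
  n_zero <- sum(sub$data == 0)
  vol_sphere <- 4 / 3 * pi * r_vox^3
  shell <- 4 * pi * r_vox^2
  expect_lt(abs(n_zero - vol_sphere), shell)
  expect_error(subtract_density(v, model, -1), "radius")
})
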