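test_that("protomer expansion emits order records per particle", {
  tab <- particle_table(sprintf("N%03d", 1:194), rot = runif(194, -180, 180),
                        tilt = runif(194, 0, 20), psi = runif(194, -180, 180),
                        half_set = rep(c("A", "B"), 97))
  rec <- expand_protomers(tab, 8, radial_offset = 270)
  expect_equal(nrow(rec), 1552)
  expect_equal(anyDuplicated(rec[, c("parent_particle_id", "asu_index")]), 0L)
  rec27 <- expand_protomers(tab[1:27, ], 8, 270)
  expect_equal(nrow(rec27), 27 * 8)
  tab_na <- tab[1:2, ]; tab_na$rot[1] <- NA
  expect_error(expand_protomers(tab_na, 8, 270), "poses")
})

test_that("a single identity particle expands to 8 protomers at 45-degree steps", {
  tab <- particle_table("p1", half_set = "A")
  rec <- expand_protomers(tab, 8, radial_offset = 272, voxel_size = 13.6)
  expect_equal(nrow(rec), 8)
  for (k in 0:7) {
    R <- euler_matrix(rec$rot[k + 1], rec$tilt[k + 1], rec$psi[k + 1])
    expect_lt(porescope:::rotation_distance(R, euler_matrix(c(45 * k, 0, 0))),
              1e-6)
    phi <- 45 * k * pi / 180
    expect_equal(c(rec$x[k + 1], rec$y[k + 1], rec$z[k + 1]),
                 20 * c(cos(phi), sin(phi), 0), tolerance = 1e-9)
  }
})

test_that("exclusion rules keep counts auditable and break ties deterministically", {
  tab <- particle_table(sprintf("N%02d", 1:27), half_set = "A")
  rec <- expand_protomers(tab, 8, 270)
  set.seed(3); rec$cc <- runif(nrow(rec))
  ex <- exclude_protomers(rec, "worst_k", 36)
  expect_equal(nrow(ex), 216)              # soft delete preserves the count
  expect_equal(sum(ex$included), 180)
  expect_true(all(ex$cc[!ex$included] <= min(ex$cc[ex$included])))
  # threshold below the minimum keeps everything
  ex2 <- exclude_protomers(rec, "cc_threshold", min(rec$cc) - 1)
  expect_true(all(ex2$included))
  # ties: equal scores drop the smallest (parent, asu) first
  rec8 <- expand_protomers(particle_table("p1", half_set = "A"), 8, 270)
  rec8$cc <- 0.5
  ex3 <- exclude_protomers(rec8, "worst_k", 3)
  expect_identical(ex3$included, c(rep(FALSE, 3), rep(TRUE, 5)))
  # monotone in the threshold
  ths <- unname(quantile(rec$cc, seq(0, 0.9, 0.15)))
  incl <- vapply(ths,
                 function(th) sum(exclude_protomers(rec, "cc_threshold",
                                                    th)$included), 0)
  expect_true(all(diff(incl) <= 0))
  expect_error(exclude_protomers(rec, "worst_k", nrow(rec)), "every record")
  expect_equal(sum(exclude_protomers(rec, "percentile", 0.25)$included),
               216 - 54)
})

test_that("class splitting maps ring presence to the depletion classes", {
  tab <- particle_table(c("a", "b", "c", "d"), half_set = "A")
  pres <- list(a = c("CR", "IR", "NR"), b = c("IR", "NR"), c = "IR",
               d = c("NR"))
  out <- split_classes(tab, pres)
  expect_identical(out$class_label, c(1L, 2L, 3L, 0L))
  pres$d <- c("CR", "IR")
  expect_warning(out2 <- split_classes(tab, pres), "unexpected")
  expect_identical(out2$class_label[4], 0L)
  expect_error(split_classes(tab, pres[1:3]), "missing")
})

test_that("class counts 27/53/83 reproduce the printed 17/32/51 split", {
  labels <- rep(1:3, c(27, 53, 83))
  rep_ <- summarize_measurements(labels)
  expect_identical(rep_$classes$percent, c(17L, 32L, 51L))
  expect_equal(sum(rep_$classes$percent), 100)
})

test_that("masked refinement recovers a small pose perturbation", {
  ph <- small_phantom()
  geo <- porescope:::phantom_geometry(small_params())
  r_off <- geo$rings$IR$r
  tab <- particle_table("p1", half_set = "A")
  rec <- expand_protomers(tab, 8, r_off, voxel_size = 13.6)
  wm <- wedge_mask(-52, 68, 32)
  # perturb protomer 3's pose before extraction: its subvolume is misaligned
  rec_pert <- rec
  R3 <- euler_matrix(rec$rot[3], rec$tilt[3], rec$psi[3]) %*%
    euler_matrix(c(4, 0, 0))
  e3 <- matrix_to_euler(R3)
  rec_pert$rot[3] <- e3[1]; rec_pert$tilt[3] <- e3[2]; rec_pert$psi[3] <- e3[3]
  stack <- extract_protomers(list(ph), "p1", rec_pert, box = 32)
  mask <- mask_spec("cylinder", radius = 150, half_height = 120,
                    soft_edge = 2)
  ref <- masked_refine(rec_pert, stack, mask, wm, step = 2, max_angle = 6,
                       max_shift = 2)
  # protomer 3 should move back by ~4 degrees; the others stay put
  R3n <- euler_matrix(ref$rot[3], ref$tilt[3], ref$psi[3])
  R3t <- euler_matrix(rec$rot[3], rec$tilt[3], rec$psi[3]) %*%
    euler_matrix(c(4, 0, 0)) %*% euler_matrix(c(-4, 0, 0))
  expect_lt(porescope:::rotation_distance(R3n, R3t), 1.5)
  for (j in c(1, 2, 4)) {
    Rj <- euler_matrix(ref$rot[j], ref$tilt[j], ref$psi[j])
    R0 <- euler_matrix(rec$rot[j], rec$tilt[j], rec$psi[j])
    expect_lt(porescope:::rotation_distance(Rj, R0), 3.5)  # < 2 grid steps
  }
  empty <- mask_spec("sphere", radius = 1e-3)
  expect_error(masked_refine(rec_pert, stack, empty, wm), "empty")
})

test_that("compose reproduces the symmetrized phantom from one protomer", {
  ph <- small_phantom()
  geo <- porescope:::phantom_geometry(small_params())
  r_off_vox <- geo$rings$IR$r / 13.6
  tab <- particle_table("p1", half_set = "A")
  rec <- expand_protomers(tab, 8, geo$rings$IR$r, voxel_size = 13.6)
  stack <- extract_protomers(list(ph), "p1", rec, box = 44)
  placement <- list(euler = c(0, 0, 0), shift = c(r_off_vox, 0, 0))
  comp <- compose_full_map(stack[[1]], 8, placement, canvas = 48,
                           blend = "max")
  expect_gt(vol_cor(comp, ph), 0.99)
  r45 <- rotate_volume(comp, c(45, 0, 0))
  expect_lt(max(abs(comp$data - r45$data)) / max(comp$data), 0.02)
  single <- compose_full_map(stack[[1]], 1, placement, canvas = 48)
  expect_lt(vol_cor(single, ph), vol_cor(comp, ph))
  expect_error(compose_full_map(stack[[1]], 8,
                                list(euler = c(0, 0, 0), shift = c(99, 0, 0)),
                                canvas = 48), "canvas")
})
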