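# Shared fixtures, built once per test run and cached.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache))
    assign(key, force(expr), envir = fixture_cache)
  get(key, envir = fixture_cache)
}

# the wild-type study phantom on the default analysis grid
wildtype_phantom <- function() cached("wt112", {
  build_phantom(npc_preset("wildtype"), 112, 13.6)
})

# a scaled-down NPC that fits a 48^3 box (for fast simulation tests)
small_params <- function(...) {
  phantom_params(membrane_pore_diameter = 40, channel_diameter = 22,
                 ir_outer_diameter = 34, cr_distal_offset = 14,
                 nr_distal_offset = 11, angle_cyto = 42, angle_nucleo = 28,
                 membrane_thickness = 6, ring_thickness = 8, ...)
}

small_phantom <- function() cached("small48", {
  build_phantom(small_params(), 48, 13.6)
})

# a mid-size NPC for the pipeline smoke test (64^3)
mid_params <- function(...) {
  phantom_params(membrane_pore_diameter = 60, channel_diameter = 33,
                 ir_outer_diameter = 46, cr_distal_offset = 24,
                 nr_distal_offset = 20, angle_cyto = 42, angle_nucleo = 28,
                 membrane_thickness = 6, ring_thickness = 9, ...)
}

# band-limited random volume (positive offset keeps the azimuthal m = 0
# harmonic well defined)
smooth_noise_volume <- function(n, seed, voxel = 10, b_soft = 8000,
                                offset = 0) {
  set.seed(seed)
  v <- density_volume(array(rnorm(n^3), rep(n, 3L)), voxel)
  v <- sharpen(v, b_factor = b_soft)   # positive B: gaussian low-pass
  v$data <- v$data + offset
  v
}

# asymmetric multi-blob object for alignment tests
blob_volume <- function(n = 32, voxel = 10, seed = 7) {
  set.seed(seed)
  pts <- cbind(runif(6, -0.25, 0.25) * n * voxel,
               runif(6, -0.25, 0.25) * n * voxel,
               runif(6, -0.25, 0.25) * n * voxel)
  simulate_map_from_model(point_model(pts, weight = runif(6, 0.5, 2)),
                          resolution = 6 * voxel, shape = n,
                          voxel_size = voxel)
}

circ_shift_array <- function(a, s) {
  d <- dim(a)
  a[((seq_len(d[1]) - 1 - s[1]) %% d[1]) + 1,
    ((seq_len(d[2]) - 1 - s[2]) %% d[2]) + 1,
    ((seq_len(d[3]) - 1 - s[3]) %% d[3]) + 1, drop = FALSE]
}

vol_cor <- function(a, b) {
  da <- if (inherits(a, "density_volume")) a$data else a
  db <- if (inherits(b, "density_volume")) b$data else b
  cor(as.vector(da), as.vector(db))
}

# brute-force Benjamini-Hochberg step-up, straight from the definition
bh_stepup <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- val
    prev <- val
  }
  q
}
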