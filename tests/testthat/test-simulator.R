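test_that("toy structures pack segments on a shell around the core", {
  st <- make_toy_structure(9, pts_per_segment = 50, seed = 2)
  expect_equal(sort(unique(st$segment)), 0:8)
  cen <- do.call(rbind, lapply(1:8, function(s) {
    colMeans(structure_coords(st)[st$segment == s, , drop = FALSE])
  }))
  expect_gt(min(dist(cen)), 3 * 9 * 0.8)   # >= 3 blob radii (min radius)
  # identical under the same seed
  expect_identical(st, make_toy_structure(9, pts_per_segment = 50,
                                          seed = 2))
  # infeasible packing is rejected with advice
  expect_error(make_toy_structure(30, seed = 1, shell_radius_A = 20),
               "infeasible")
})

test_that("compositional simulation hits the design frequencies", {
  st <- tiny_structure(n_segments = 5)
  # p_absent = 0: one complete state
  s0 <- simulate_compositional(st, 50, p_absent = 0, seed = 3)
  expect_true(all(s0$presence))
  expect_equal(length(unique(s0$state_id)), 1)

  sim <- simulate_compositional(st, 4000, p_absent = 0.5, seed = 4)
  expect_true(all(sim$presence[, 1]))
  freq <- colMeans(!sim$presence[, -1])
  se <- sqrt(0.25 / 4000)
  expect_true(all(abs(freq - 0.5) < 3 * se))
  # state id consistent with the presence rows
  recomputed <- as.integer(sim$presence[, -1] %*% 2^(0:3))
  expect_identical(sim$state_id, recomputed)
})

test_that("motion simulation is rigid and matches its analytic RMSD", {
  st <- make_toy_structure(4, pts_per_segment = 80, seed = 5,
                           blob_radius_A = 11, shell_radius_A = 36)
  regions <- list(1L)
  axes <- list(list(point = c(10, 0, 0), direction = c(0, 0, 1)))
  # zero range -> zero displacement
  s0 <- simulate_motion(st, regions, axes, 0, 10, seed = 6)
  expect_lt(max(abs(motion_displacement(s0, 3))), 1e-12)

  sim <- simulate_motion(st, regions, axes, 70, 4000, seed = 7)
  expect_true(all(abs(sim$angles) <= 35))
  # rigidity: distances to the axis are preserved
  co0 <- structure_coords(st)
  co1 <- particle_coords(sim, 5)$coords
  sel <- st$segment == 1
  dist_axis <- function(co) {
    rel <- sweep(co[sel, , drop = FALSE], 2, c(10, 0, 0))
    sqrt(rel[, 1]^2 + rel[, 2]^2)
  }
  expect_lt(max(abs(dist_axis(co1) - dist_axis(co0))), 1e-9)
  # displacements vanish outside the moving region
  expect_true(all(motion_displacement(sim, 5)[!sel, ] == 0))

  # Monte-Carlo mean per-particle RMSD vs the closed form
  rms <- vapply(seq_len(4000), function(i) {
    d <- motion_displacement(sim, i)
    sqrt(mean(rowSums(d^2)))
  }, numeric(1))
  expect_lt(abs(mean(rms) -
                  expected_motion_rmsd(st, regions, axes, 70)) /
              mean(rms), 0.02)

  # calibration inverts the expectation
  rng <- calibrate_angle_range(st, regions, axes, 5)
  expect_equal(expected_motion_rmsd(st, regions, axes, rng), 5,
               tolerance = 1e-3)

  expect_error(simulate_motion(st, list(1L, 1L),
                               c(axes, axes), 30, 5), "disjoint")
})

test_that("rendered particles honour SNR, orientations and determinism", {
  st <- tiny_structure(n_segments = 4)
  sim <- simulate_compositional(st, 300, 0.5, seed = 8)
  clean <- render_particles(sim, D = 32, snr = Inf, seed = 9)
  noisy <- render_particles(sim, D = 32, snr = 0.5, seed = 9)

  # noise-free image equals the CTF-modulated projection of the atoms
  i <- 7
  pc <- particle_coords(sim, i)
  md <- clean$metadata
  g <- gmm(pc$coords / box_size(st), pc$weights,
           rep(1.6 / 32, nrow(pc$coords)))
  fh <- project_gmm(g, euler_to_quat(md$rot[i], md$tilt[i], md$psi[i]),
                    c(0, 0), 32)
  ctf <- ctf_params(defocus = md$defocus[i], voltage = md$voltage[i],
                    cs = md$cs[i],
                    amplitude_contrast = md$amplitude_contrast[i],
                    pixel_size = md$pixel_size[i])
  expect_lt(max(abs(clean$images[, , i] -
                      image_from_fourier(ctf_apply(fh, ctf)))), 1e-8)

  # empirical SNR within 10% of requested
  noise <- noisy$images - clean$images
  snr_hat <- mean(vapply(seq_len(300), function(j) {
    stats::var(as.vector(clean$images[, , j])) /
      stats::var(as.vector(noise[, , j]))
  }, numeric(1)))
  expect_lt(abs(snr_hat - 0.5) / 0.5, 0.1)

  # pure function of (config, seed)
  again <- render_particles(sim, D = 32, snr = 0.5, seed = 9)
  expect_identical(noisy$images, again$images)
  expect_identical(noisy$metadata, again$metadata)
})

test_that("ground truth round-trips through the sidecar format", {
  st <- tiny_structure(n_segments = 4)
  sim <- simulate_compositional(st, 20, 0.5, seed = 10)
  gt <- tidy(sim)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(gt, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  rd <- utils::read.delim(path)
  expect_equal(rd$state_id, gt$state_id)
  expect_equal(as.matrix(rd[, -(1:2)]), as.matrix(gt[, -(1:2)]),
               ignore_attr = TRUE)
})
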