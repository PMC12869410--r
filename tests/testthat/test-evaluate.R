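comp_fixture <- function(n_particles = 400, seed = 61) {
  st <- tiny_structure(n_segments = 5)
  sim <- simulate_compositional(st, n_particles, 0.5, seed = seed)
  neutral <- seed_gmm_from_structure(st, 60, width0 = 0.03, seed = seed)
  gmap <- map_gaussians_to_atoms(neutral, st)
  list(st = st, sim = sim, neutral = neutral, gmap = gmap)
}

test_that("amplitude accuracy is 1 on oracle outputs and 0 when inverted", {
  fx <- comp_fixture()
  orc <- oracle_outputs(fx$sim, fx$gmap, fx$neutral)
  acc <- amplitude_accuracy(orc, fx$gmap, fx$sim, threshold = 0.5)
  expect_equal(acc$accuracy, 1)
  expect_true(all(acc$per_segment$accuracy == 1))
  expect_false(0L %in% acc$per_segment$segment)

  inv <- orc
  inv$gate <- 1 - orc$gate
  acc0 <- amplitude_accuracy(inv, fx$gmap, fx$sim, threshold = 0.5)
  expect_equal(acc0$accuracy, 0)
})

test_that("random amplitudes score at the binomial null", {
  fx <- comp_fixture(n_particles = 600)
  orc <- oracle_outputs(fx$sim, fx$gmap, fx$neutral)
  set.seed(62)
  rnd <- orc
  rnd$gate <- matrix(runif(length(orc$gate), 0, 1),
                     nrow(orc$gate))          # present iff gate >= 0.5
  acc <- amplitude_accuracy(rnd, fx$gmap, fx$sim, threshold = 0.5)
  n_pred <- sum(fx$gmap$segment != 0) * 600
  expect_gt(n_pred, 1e4)
  se <- sqrt(0.25 / n_pred)
  expect_lt(abs(acc$accuracy - 0.5), 3 * se)
})

test_that("accuracy peaks at the histogram valley on separable outputs", {
  fx <- comp_fixture()
  orc <- oracle_outputs(fx$sim, fx$gmap, fx$neutral)
  set.seed(63)
  noisy <- orc
  noisy$gate <- pmin(pmax(orc$gate +
                            matrix(rnorm(length(orc$gate), sd = 0.15),
                                   nrow(orc$gate)), 0), 2)
  a_mid <- amplitude_accuracy(noisy, fx$gmap, fx$sim, 0.5)$accuracy
  a_lo <- amplitude_accuracy(noisy, fx$gmap, fx$sim, 0.05)$accuracy
  a_hi <- amplitude_accuracy(noisy, fx$gmap, fx$sim, 1.6)$accuracy
  expect_gte(a_mid, a_lo)
  expect_gte(a_mid, a_hi)
})

test_that("amplitude accuracy rejects unmapped Gaussians", {
  fx <- comp_fixture(n_particles = 20)
  orc <- oracle_outputs(fx$sim, fx$gmap, fx$neutral)
  bad_map <- fx$gmap[-1, ]
  expect_error(amplitude_accuracy(orc, bad_map, fx$sim), "mapped")
})

motion_fixture <- function(n_particles = 10, seed = 64) {
  st <- make_toy_structure(4, pts_per_segment = 33, seed = seed,
                           blob_radius_A = 11, shell_radius_A = 36)
  regions <- list(1L)
  axes <- default_motion_axes(st, regions)
  sim <- simulate_motion(st, regions, axes, 60, n_particles, seed = seed)
  # one Gaussian per atom: nearest-Gaussian transfer becomes exact
  neutral <- seed_gmm_from_structure(st, nrow(st), width0 = 0.03,
                                     seed = seed)
  gmap <- map_gaussians_to_atoms(neutral, st)
  list(st = st, sim = sim, neutral = neutral, gmap = gmap)
}

oracle_motion_outputs <- function(fx, lambda = 1) {
  n <- fx$sim$n_particles
  N <- nrow(fx$neutral$centers)
  box_A <- box_size(fx$st)
  atom_of <- oracle_nearest(fx$neutral$centers, structure_coords_box(fx$st))
  dc <- array(0, c(n, N, 3))
  for (i in seq_len(n)) {
    dc[i, , ] <- lambda * motion_displacement(fx$sim, i)[atom_of, ] / box_A
  }
  structure(list(latent = matrix(0, n, 0), d_center = dc,
                 d_amplitude = matrix(0, n, N),
                 d_sigma = matrix(0, n, N),
                 gate = matrix(1, n, N), neutral = fx$neutral,
                 box_size_A = box_A, decoder_type = "oracle"),
            class = "ptgmm_particles")
}

test_that("motion RMSD is zero at truth, the baseline at zero, quadratic in between", {
  fx <- motion_fixture()
  r1 <- motion_rmsd(oracle_motion_outputs(fx, 1), fx$neutral, fx$gmap,
                    fx$sim)
  expect_lt(attr(r1, "mean_rmsd"), 1e-9)

  r0 <- motion_rmsd(oracle_motion_outputs(fx, 0), fx$neutral, fx$gmap,
                    fx$sim)
  truth_mag <- vapply(seq_len(fx$sim$n_particles), function(i) {
    sqrt(mean(rowSums(motion_displacement(fx$sim, i)^2)))
  }, numeric(1))
  expect_equal(r0$rmsd, truth_mag, tolerance = 1e-12)
  expect_equal(r0$rmsd, r0$baseline, tolerance = 1e-12)

  # rmsd(lambda) = |1 - lambda| * baseline for scaled-truth predictions
  r2 <- motion_rmsd(oracle_motion_outputs(fx, 2), fx$neutral, fx$gmap,
                    fx$sim)
  expect_equal(r2$rmsd, r0$baseline, tolerance = 1e-9)
  rh <- motion_rmsd(oracle_motion_outputs(fx, 0.5), fx$neutral, fx$gmap,
                    fx$sim)
  expect_equal(rh$rmsd, 0.5 * r0$baseline, tolerance = 1e-9)
})

test_that("vectorized RMSD equals an explicit loop", {
  fx <- motion_fixture()
  out <- oracle_motion_outputs(fx, 0.7)
  res <- motion_rmsd(out, fx$neutral, fx$gmap, fx$sim)
  box_A <- box_size(fx$st)
  atoms <- structure_coords_box(fx$st)
  for (i in seq_len(5)) {
    tr <- motion_displacement(fx$sim, i)
    tot <- 0
    for (a in seq_len(nrow(atoms))) {
      d2 <- colSums((t(fx$neutral$centers) - atoms[a, ])^2)
      gbest <- which.min(d2)
      pred <- out$d_center[i, gbest, ] * box_A
      tot <- tot + sum((pred - tr[a, ])^2)
    }
    expect_lt(abs(res$rmsd[i] - sqrt(tot / nrow(atoms))), 1e-9)
  }
})

test_that("motion RMSD rejects a box-size mismatch", {
  fx <- motion_fixture(n_particles = 3)
  out <- oracle_motion_outputs(fx)
  out$box_size_A <- out$box_size_A * 2
  expect_error(motion_rmsd(out, fx$neutral, fx$gmap, fx$sim), "box size")
})
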