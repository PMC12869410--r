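interp_fixture <- function(n_particles = 600, n_segments = 9,
                           n_gaussians = 140, seed = 81) {
  st <- make_toy_structure(n_segments, pts_per_segment = 60, seed = seed)
  sim <- simulate_compositional(st, n_particles, 0.5, seed = seed + 1)
  neutral <- seed_gmm_from_structure(st, n_gaussians, width0 = 0.03,
                                     seed = seed + 2)
  gmap <- map_gaussians_to_atoms(neutral, st)
  orc <- oracle_outputs(sim, gmap, neutral)
  list(st = st, sim = sim, neutral = neutral, gmap = gmap, orc = orc)
}

test_that("feature matrices carry the decoder outputs verbatim", {
  fx <- interp_fixture(n_particles = 2, n_gaussians = 30, n_segments = 3)
  f <- build_feature_matrix(fx$orc, "amplitude", standardize = FALSE)
  expect_equal(dim(f), c(30, 2))
  expect_equal(unclass(f), t(fx$orc$gate), ignore_attr = TRUE)
  # subsample cap beyond n keeps all particles in order
  expect_equal(attr(f, "particles"), 1:2)
})

test_that("same-segment Gaussians correlate more strongly than cross-segment", {
  fx <- interp_fixture(n_particles = 400)
  f <- build_feature_matrix(fx$orc, "amplitude", standardize = FALSE)
  seg <- fx$gmap$segment
  s_a <- which(seg == 1); s_b <- which(seg == 2)
  r_same <- cor(f[s_a[1], ], f[s_a[2], ])
  r_cross <- cor(f[s_a[1], ], f[s_b[1], ])
  expect_gt(r_same, r_cross)
  expect_gt(r_same, 0.99)
  expect_lt(abs(r_cross), 0.2)
})

test_that("segment_gmm recovers the true regions from oracle outputs", {
  fx <- interp_fixture()
  f <- build_feature_matrix(fx$orc, "amplitude", seed = 1)
  reg <- segment_gmm(f, seed = 2)
  expect_s3_class(reg, "region_set")
  m <- match_regions_to_segments(reg, fx$gmap)
  expect_equal(m$n_matched, 8)
  if (requireNamespace("mclust", quietly = TRUE)) {
    keep <- reg$region != -1L
    ari <- mclust::adjustedRandIndex(reg$region[keep],
                                     fx$gmap$segment[keep])
    expect_gt(ari, 0.9)
  }
})

test_that("segment_gmm is reproducible and permutation-consistent", {
  fx <- interp_fixture(n_particles = 250, n_segments = 5,
                       n_gaussians = 80)
  f <- build_feature_matrix(fx$orc, "amplitude", seed = 1)
  r1 <- segment_gmm(f, seed = 9)
  r2 <- segment_gmm(f, seed = 9)
  expect_identical(r1$region, r2$region)

  set.seed(10)
  perm <- sample(nrow(f))
  fp <- f[perm, ]
  class(fp) <- class(f)
  rp <- segment_gmm(fp, seed = 9)
  # same partition after unshuffling (labels may be renumbered)
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_gt(mclust::adjustedRandIndex(rp$region, r1$region[perm]), 0.95)
  }
})

test_that("region-focused particle classification recovers segment presence", {
  fx <- interp_fixture(n_particles = 300, n_segments = 5,
                       n_gaussians = 80)
  f <- build_feature_matrix(fx$orc, "amplitude", seed = 1)
  reg <- segment_gmm(f, seed = 2)
  m <- match_regions_to_segments(reg, fx$gmap)
  s <- m$table$segment[m$table$matched][1]
  rlab <- m$table$region[m$table$segment == s]
  emb <- focus_embed_particles(fx$orc, reg, rlab, k = 2, seed = 3)
  truth <- fx$sim$presence[, s + 1]
  tab <- table(emb$class, truth)
  acc <- max(sum(diag(tab)), sum(tab[1, 2], tab[2, 1])) / sum(tab)
  expect_gt(acc, 0.95)

  # k = 1 puts everything in one class
  e1 <- focus_embed_particles(fx$orc, reg, rlab, k = 1, seed = 3)
  expect_true(all(e1$class == 1L))
  expect_error(focus_embed_particles(fx$orc, reg, region = 999),
               "empty region")
})

test_that("a single moving region embeds particles on a curve tracking angle", {
  st <- make_toy_structure(4, pts_per_segment = 60, seed = 83,
                           blob_radius_A = 11, shell_radius_A = 36)
  regions <- list(1L)
  axes <- default_motion_axes(st, regions)
  sim <- simulate_motion(st, regions, axes, 70, 250, seed = 84)
  neutral <- seed_gmm_from_structure(st, nrow(st), width0 = 0.03,
                                     seed = 85)
  box_A <- box_size(st)
  n <- sim$n_particles; N <- nrow(neutral$centers)
  dc <- array(0, c(n, N, 3))
  atom_of <- oracle_nearest(neutral$centers, structure_coords_box(st))
  for (i in seq_len(n)) {
    dc[i, , ] <- motion_displacement(sim, i)[atom_of, ] / box_A
  }
  orc <- structure(list(latent = matrix(0, n, 0), d_center = dc,
                        d_amplitude = matrix(0, n, N),
                        d_sigma = matrix(0, n, N),
                        gate = matrix(1, n, N), neutral = neutral,
                        box_size_A = box_A, decoder_type = "oracle"),
                   class = "ptgmm_particles")
  regset <- tibble::tibble(gaussian = seq_len(N),
                           region = ifelse(st$segment == 1, 1L, 2L),
                           emb1 = 0, emb2 = 0)
  emb <- focus_embed_particles(orc, regset, 1, k = 3,
                               channel = "motion", seed = 5)
  expect_gt(oracle_dcor(cbind(emb$emb1, emb$emb2), sim$angles[, 1]), 0.9)
})

test_that("class difference volumes localize, cancel and antisymmetrize", {
  fx <- interp_fixture(n_particles = 200, n_segments = 5,
                       n_gaussians = 80)
  s <- 2L
  classes <- ifelse(fx$sim$presence[, s + 1], 1L, 2L)
  dv <- class_difference_volume(fx$orc, classes, fx$neutral,
                                grid_size = 40)
  # mass concentrated in the toggled segment's bounding box
  gs <- 40
  sel <- fx$st$segment == s
  bb <- apply(structure_coords_box(fx$st)[sel, ], 2, range)
  pad <- 0.06
  ax <- (seq_len(gs) - 1 - gs / 2) / gs
  inx <- ax >= bb[1, 1] - pad & ax <= bb[2, 1] + pad
  iny <- ax >= bb[1, 2] - pad & ax <= bb[2, 2] + pad
  inz <- ax >= bb[1, 3] - pad & ax <= bb[2, 3] + pad
  frac <- sum(abs(dv$volume[inx, iny, inz])) / sum(abs(dv$volume))
  expect_gt(frac, 0.8)

  # identical classes -> zero volume; swapped classes -> negated volume
  same <- class_difference_volume(fx$orc, rep(1L, 200), fx$neutral, 24,
                                  class_a = 1, class_b = 1)
  expect_equal(max(abs(same$volume)), 0)
  swap <- class_difference_volume(fx$orc, classes, fx$neutral, 40,
                                  class_a = 2, class_b = 1)
  expect_equal(swap$volume, -dv$volume)
  expect_error(class_difference_volume(fx$orc, classes, fx$neutral, 24,
                                       class_a = 7), "no particles")
})

test_that("duplicating all Gaussians preserves the region structure", {
  fx <- interp_fixture(n_particles = 250, n_segments = 5,
                       n_gaussians = 70)
  f <- build_feature_matrix(fx$orc, "amplitude", seed = 1)
  r1 <- segment_gmm(f, seed = 4, min_pts = 5)
  fd <- rbind(unclass(f), unclass(f) +
                matrix(rnorm(length(f), sd = 1e-6), nrow(f)))
  r2 <- segment_gmm(fd, seed = 4, min_pts = 10)
  n1 <- length(setdiff(unique(r1$region), -1L))
  n2 <- length(setdiff(unique(r2$region), -1L))
  expect_equal(n2, n1)
})

test_that("direct-Fourier backprojection localizes a single blob", {
  st <- protein_structure(matrix(rnorm(60, sd = 3), 20, 3) + 15,
                          rep(c(0L, 1L), each = 10), box_size_A = 96)
  sim <- simulate_compositional(st, 160, p_absent = 0, seed = 7)
  stack <- render_particles(sim, D = 32, snr = Inf, seed = 8)
  vol <- backproject_particles(stack)
  pk <- which(vol == max(vol), arr.ind = TRUE)[1, ]
  # blob centre ~ (15,15,15) A = 0.156 box -> voxel 16 + 5 = 21
  expect_true(all(abs(pk - 22) <= 2))
  # mass concentrated near the blob, not at the mirrored position
  expect_gt(vol[21, 21, 21], 3 * abs(vol[11, 11, 11]))
})
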