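make_tiny_decoder <- function(N = 12, seed = 7) {
  set.seed(seed)
  centers <- matrix(runif(N * 3, -0.3, 0.3), N, 3)
  h <- build_hierarchy(centers, level_sizes = c(4, 8, N), k_attn = 3,
                       seed = 1)
  cfg <- decoder_config(channels = c(8, 6, 5), latent_dim = 3,
                        seed_hidden = 10, pos_hidden = 4,
                        resid_channels = 3)
  list(h = h, dec = init_pt_decoder(h, cfg, seed = seed + 1),
       centers = centers)
}

test_that("latent_seed maps to the (B, P1, C) tensor and is continuous", {
  set.seed(41)
  w <- list(l1 = lin_init(4, 16), l2 = lin_init(16, 64 * 256))
  Z <- matrix(rnorm(8), 2, 4)
  X <- latent_seed(Z, w, n_points = 64, channels = 256)
  expect_equal(dim(X), c(2 * 64, 256))

  # zero weights -> all-zero output
  w0 <- param_map(w, function(x) x * 0)
  expect_true(all(latent_seed(Z, w0, 64, 256) == 0))

  # continuity in the latent
  for (d in c(1e-2, 1e-4, 1e-6)) {
    Xd <- latent_seed(Z + d, w, 64, 256)
    expect_lt(max(abs(Xd - X)), 1e3 * d)
  }
})

test_that("attention is uniform over identical neighbours", {
  C <- 6; k <- 4; P <- 8
  pts <- matrix(0.1, P, 3)                 # all positions identical
  nbr <- matrix(rep(1:k, each = P), P, k)  # arbitrary but fixed
  set.seed(42)
  w <- pt_block_weights(C, 4)
  X <- matrix(rep(rnorm(C), each = P), P, C)  # identical features
  fw <- pt_block_fwd(X, w, block_geom(pts, nbr), 1, engine = "r")
  expect_lt(max(abs(fw$cache$A - 1 / k)), 1e-12)
})

test_that("pt_block matches the naive loop oracle on both engines", {
  set.seed(43)
  P <- 50; k <- 8; C <- 10; B <- 2
  pts <- matrix(runif(P * 3, -0.5, 0.5), P, 3)
  nbr <- knn_index(pts, pts, k)
  w <- pt_block_weights(C, 5)
  X <- matrix(rnorm(B * P * C), B * P, C)
  want <- oracle_pt_block(X, pts, nbr, w, B)
  for (engine in c("r", "cpp")) {
    got <- pt_block_fwd(X, w, block_geom(pts, nbr), B, engine)$out
    expect_lt(max(abs(got - want)), 1e-5)
  }
})

test_that("pt_block is equivariant under point permutation", {
  set.seed(44)
  P <- 30; k <- 5; C <- 7
  pts <- matrix(runif(P * 3), P, 3)
  nbr <- knn_index(pts, pts, k)
  w <- pt_block_weights(C, 4)
  X <- matrix(rnorm(P * C), P, C)
  out <- pt_block(X, pts, nbr, w)
  perm <- sample(P)
  inv <- order(perm)
  nbr_p <- matrix(inv[nbr[perm, ]], P, k)
  out_p <- pt_block(X[perm, ], pts[perm, ], nbr_p, w)
  expect_lt(max(abs(out_p - out[perm, ])), 1e-9)
})

test_that("transition_up interpolates as the loop oracle, conserving constants", {
  set.seed(45)
  P1 <- 12; P2 <- 40; C1 <- 6; C2 <- 5; B <- 2
  coarse <- matrix(runif(P1 * 3), P1, 3)
  fine <- matrix(runif(P2 * 3), P2, 3)
  tab <- interp_table(fine, coarse)
  w <- lin_init(C1, C2)
  Xc <- matrix(rnorm(B * P1 * C1), B * P1, C1)
  got <- transition_up(Xc, tab$idx, tab$weight, w, batch = B)
  want <- oracle_transition_up(Xc, tab$idx, tab$weight, w, B)
  expect_lt(max(abs(got - want)), 1e-6)

  # constant coarse features -> constant fine features
  Xconst <- matrix(rep(rnorm(C1), each = B * P1), B * P1, C1)
  outc <- transition_up(Xconst, tab$idx, tab$weight, w, batch = B)
  expect_lt(max(apply(outc, 2, function(col) diff(range(col)))), 1e-9)

  # a fine point coincident with a coarse point copies its feature
  fine2 <- rbind(coarse[3, ], fine)
  tab2 <- interp_table(fine2, coarse)
  out2 <- transition_up(Xc[1:P1, , drop = FALSE], tab2$idx, tab2$weight,
                        w, batch = 1)
  proj <- Xc[1:P1, , drop = FALSE] %*% w$W +
    matrix(w$b, P1, C2, byrow = TRUE)
  expect_lt(max(abs(out2[1, ] - proj[3, ])), 1e-9)
})

test_that("decode yields 5 bounded channels and the identity at zero head", {
  td <- make_tiny_decoder()
  Z <- matrix(rnorm(6), 2, 3)
  out <- decode(Z, td$h, td$dec)
  expect_equal(dim(out$d_center), c(2, 12, 3))
  expect_equal(dim(out$d_amplitude), c(2, 12))
  expect_equal(dim(out$d_sigma), c(2, 12))
  expect_true(all(abs(out$d_center) <= 0.1))
  expect_true(all(abs(out$d_sigma) <= 0.5))

  # zero head -> zero deltas -> neutral model back
  dec0 <- td$dec
  dec0$params$head$W[] <- 0
  dec0$params$head$b[] <- 0
  out0 <- decode(Z, td$h, dec0)
  expect_true(all(out0$d_center == 0))
  neutral <- gmm(td$centers, rep(1, 12), rep(0.03, 12))
  expect_equal(apply_deltas(neutral, out0, b = 1), neutral)

  # determinism and batch-order invariance
  out2 <- decode(Z, td$h, td$dec)
  expect_identical(out, out2)
  outp <- decode(Z[2:1, ], td$h, td$dec)
  expect_equal(outp$d_amplitude, out$d_amplitude[2:1, ], tolerance = 1e-12)

  # size mismatch between decoder and hierarchy is rejected
  other <- build_hierarchy(matrix(runif(30), 10, 3),
                           level_sizes = c(4, 6, 10), k_attn = 3)
  expect_error(decode(Z, other, td$dec), "disagree")
})

test_that("decoder backprop matches finite differences end to end", {
  td <- make_tiny_decoder()
  B <- 2
  Z <- matrix(rnorm(B * 3), B, 3)
  set.seed(9)
  N <- 12
  w1 <- array(rnorm(B * N * 3), c(B, N, 3))
  w2 <- matrix(rnorm(B * N), B, N)
  w3 <- matrix(rnorm(B * N), B, N)
  lossof <- function(out) sum(w1 * out$d_center) +
    sum(w2 * out$d_amplitude) + sum(w3 * out$d_sigma)
  fw <- decode_fwd(Z, td$dec, td$h)
  bw <- decode_bwd(fw$cache, td$dec, td$h,
                   list(d_center = w1, d_amplitude = w2, d_sigma = w3))
  v0 <- param_flatten(td$dec$params)
  gv <- param_flatten(bw$grad)
  set.seed(10)
  eps <- 1e-5
  for (i in sample(length(v0), 25)) {
    dp <- td$dec; dm <- td$dec
    vp <- v0; vp[i] <- vp[i] + eps
    vm <- v0; vm[i] <- vm[i] - eps
    dp$params <- param_unflatten(td$dec$params, vp)
    dm$params <- param_unflatten(td$dec$params, vm)
    fd <- (lossof(decode_fwd(Z, dp, td$h)$out) -
             lossof(decode_fwd(Z, dm, td$h)$out)) / (2 * eps)
    expect_lt(abs(fd - gv[i]) / max(abs(fd), 1e-6), 1e-3)
  }
  # latent gradient
  for (j in 1:3) {
    Zp <- Z; Zp[1, j] <- Zp[1, j] + eps
    Zm <- Z; Zm[1, j] <- Zm[1, j] - eps
    fd <- (lossof(decode_fwd(Zp, td$dec, td$h)$out) -
             lossof(decode_fwd(Zm, td$dec, td$h)$out)) / (2 * eps)
    expect_lt(abs(fd - bw$dZ[1, j]) / max(abs(fd), 1e-6), 1e-3)
  }
})

test_that("apply_deltas applies centres additively and gates amplitudes", {
  neutral <- tiny_gmm()
  N <- nrow(neutral$centers)
  set.seed(46)
  delta <- list(d_center = array(rnorm(N * 3, sd = 0.01), c(1, N, 3)),
                d_amplitude = matrix(runif(N, -0.5, 0.5), 1, N),
                d_sigma = matrix(runif(N, -0.3, 0.3), 1, N))
  out <- apply_deltas(neutral, delta)
  expect_equal(out$centers, neutral$centers + delta$d_center[1, , ])
  expect_equal(out$amplitudes,
               neutral$amplitudes * (1 + delta$d_amplitude[1, ]))
  expect_equal(out$widths, neutral$widths * exp(delta$d_sigma[1, ]))

  # gate floor switches a segment off entirely
  delta$d_amplitude[1, 3] <- -1
  expect_equal(apply_deltas(neutral, delta)$amplitudes[3], 0)
  # zero delta is the identity
  z <- list(d_center = array(0, c(1, N, 3)),
            d_amplitude = matrix(0, 1, N), d_sigma = matrix(0, 1, N))
  expect_equal(apply_deltas(neutral, z), neutral)
})
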