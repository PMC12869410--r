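test_that("project_gmm matches the closed form at DC and the geometry", {
  sig <- 0.04
  g <- gmm(matrix(0, 1, 3), 1, sig)
  fh <- project_gmm(g, c(1, 0, 0, 0), c(0, 0), 32)
  expect_equal(Re(fh[1, 1]), 2 * pi * sig^2, tolerance = 1e-12)
  expect_lt(max(abs(Im(fh[1, ]))), 1e-12)   # zero phase at centre

  # rotating an off-centre Gaussian by 90 deg about z rotates the image
  g2 <- gmm(matrix(c(0.15, 0, 0), 1, 3), 1, sig)
  i1 <- image_from_fourier(project_gmm(g2, euler_to_quat(90, 0, 0),
                                       c(0, 0), 32))
  # (x, y) -> (-y, x): peak moves from +x to +y
  p1 <- which(i1 == max(i1), arr.ind = TRUE)
  ax <- ((0:31) - 16) / 32
  expect_lt(abs(ax[p1[1]]), 0.04)           # x near 0
  expect_gt(ax[p1[2]], 0.1)                 # y near +0.15
})

test_that("Fourier projection equals brute-force real-space rendering", {
  set.seed(11)
  D <- 48
  g <- gmm(matrix(runif(18, -0.25, 0.25), 6, 3),
           runif(6, 0.5, 1.5), runif(6, 1.5 / D, 3 / D))
  q <- euler_to_quat(25, 70, -40)
  sh <- c(1.5, -2)
  img <- image_from_fourier(project_gmm(g, q, sh, D))
  oracle <- oracle_projection_image(g, q, sh, D)
  expect_lt(max(abs(img - oracle)), 1e-4 * max(oracle))
})

test_that("project_gmm is translation-equivariant in Fourier phase", {
  set.seed(12)
  D <- 32
  g <- tiny_gmm()
  q <- euler_to_quat(10, 30, 5)
  s <- c(2.3, -1.1)
  f0 <- project_gmm(g, q, c(0, 0), D)
  f1 <- project_gmm(g, q, s, D)
  gr <- freq_grid(D)
  phase <- exp(-2i * pi * (gr$kx * s[1] + gr$ky * s[2]) / D)
  expect_lt(max(abs(f1 - f0 * phase)), 1e-12)
})

test_that("CTF follows the stated convention", {
  D <- 48
  k2 <- freq_grid(D)$k2
  # pure amplitude contrast: CTF = -1 everywhere
  c1 <- ctf_params(defocus = 0, cs = 0, amplitude_contrast = 1,
                   b_factor = 0, pixel_size = 2)
  expect_true(all(abs(ctf_eval(c1, k2, D) + 1) < 1e-12))

  # zero crossings match the roots of chi = n*pi found by a root finder
  cp <- ctf_params(defocus = 1.5, voltage = 300, cs = 2.7,
                   amplitude_contrast = 0, pixel_size = 1.5)
  lambda <- 12.2639 / sqrt(3e5 + 0.97845e-6 * 9e10)
  chi <- function(g2) pi * lambda * 1.5e4 * g2 -
    (pi / 2) * 2.7e7 * lambda^3 * g2^2
  for (n in 1:3) {
    root_g2 <- uniroot(function(g2) chi(g2) - n * pi, c(1e-8, 0.05),
                       tol = 1e-14)$root
    k2r <- root_g2 * (D * 1.5)^2
    expect_lt(abs(ctf_eval(cp, k2r, D)), 1e-8)
  }

  # positive B-factor strictly shrinks every non-DC amplitude
  cB <- ctf_params(defocus = 1.5, b_factor = 80, pixel_size = 1.5)
  c0 <- ctf_params(defocus = 1.5, b_factor = 0, pixel_size = 1.5)
  k2v <- 1:20
  expect_true(all(abs(ctf_eval(cB, k2v, D)) < abs(ctf_eval(c0, k2v, D))))
})

test_that("frc_loss hits its bounds and the white-noise null", {
  set.seed(13)
  D <- 64
  img <- matrix(rnorm(D * D), D, D)
  o <- fourier_from_image(img)
  expect_equal(frc_loss(o, o), -1, tolerance = 1e-6)
  expect_equal(frc_loss(-o, o), 1, tolerance = 1e-6)

  # per-ring positive rescaling invariance
  g <- freq_grid(D)
  scale <- (1 + g$ring)^0.7
  expect_lt(abs(frc_loss(o * scale, o) + 1), 1e-6)

  # Monte-Carlo null: predicted vs white noise
  pred <- fourier_from_image(oracle_projection_image(tiny_gmm(),
                                                     c(1, 0, 0, 0),
                                                     c(0, 0), D))
  losses <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    frc_loss(pred, fourier_from_image(matrix(rnorm(D * D), D, D)))
  }, numeric(1))
  expect_lt(abs(mean(losses)), 0.05)

  # all-zero observed contributes 0 per ring
  expect_equal(frc_loss(o, o * 0), 0)
})

test_that("autodiff gradients of the full forward chain match finite differences", {
  set.seed(14)
  D <- 32
  N <- 4
  centers <- matrix(runif(N * 3, -0.2, 0.2), N, 3)
  amps <- runif(N, 0.5, 1.5)
  widths <- runif(N, 0.025, 0.05)
  Rm <- quat_to_matrix(euler_to_quat(15, 55, -25))
  m <- ring_mask(D, 12)
  ctf <- ctf_params(defocus = 1.2, pixel_size = 3)
  cv <- ctf_eval(ctf, m$k2, D)
  set.seed(15)
  obs <- complex(real = rnorm(length(m$idx)),
                 imaginary = rnorm(length(m$idx)))
  lossfn <- function(ctr, am, wd, engine) {
    pp <- project_particle(ctr, am, wd, Rm, c(0.7, -0.4), m, engine)
    frc_loss_masked(pp$F * cv, obs, m$ring)$loss
  }
  for (engine in c("r", "cpp")) {
    pp <- project_particle(centers, amps, widths, Rm, c(0.7, -0.4), m,
                           engine)
    fl <- frc_loss_masked(pp$F * cv, obs, m$ring)
    gr <- pp$grad(fl$grad() * cv)
    eps <- 1e-6
    # one coordinate of each parameter class
    cp <- centers; cp[2, 1] <- cp[2, 1] + eps
    cm <- centers; cm[2, 1] <- cm[2, 1] - eps
    fd_c <- (lossfn(cp, amps, widths, engine) -
               lossfn(cm, amps, widths, engine)) / (2 * eps)
    expect_lt(abs(fd_c - gr$d_centers[2, 1]) / abs(fd_c), 1e-3)
    ap <- amps; ap[3] <- ap[3] + eps
    am2 <- amps; am2[3] <- am2[3] - eps
    fd_a <- (lossfn(centers, ap, widths, engine) -
               lossfn(centers, am2, widths, engine)) / (2 * eps)
    expect_lt(abs(fd_a - gr$d_amps[3]) / max(abs(fd_a), 1e-8), 1e-3)
    wp <- widths; wp[1] <- wp[1] + eps
    wm <- widths; wm[1] <- wm[1] - eps
    fd_w <- (lossfn(centers, amps, wp, engine) -
               lossfn(centers, amps, wm, engine)) / (2 * eps)
    expect_lt(abs(fd_w - gr$d_widths[1]) / abs(fd_w), 1e-3)
  }
})

test_that("compiled and reference projection paths agree exactly", {
  set.seed(16)
  m <- ring_mask(48, 20)
  ctr <- matrix(runif(60, -0.3, 0.3), 20, 3)
  am <- runif(20); wd <- runif(20, 0.02, 0.06)
  Rm <- quat_to_matrix(euler_to_quat(33, 75, -12))
  pr <- project_particle(ctr, am, wd, Rm, c(0.5, -1), m, engine = "r")
  pc <- project_particle(ctr, am, wd, Rm, c(0.5, -1), m, engine = "cpp")
  expect_lt(max(abs(pr$F - pc$F)), 1e-10)
  gbar <- complex(real = rnorm(length(m$idx)),
                  imaginary = rnorm(length(m$idx)))
  gr <- pr$grad(gbar); gc <- pc$grad(gbar)
  expect_lt(max(abs(gr$d_centers - gc$d_centers)), 1e-9)
  expect_lt(max(abs(gr$d_amps - gc$d_amps)), 1e-9)
  expect_lt(max(abs(gr$d_widths - gc$d_widths)), 1e-9)
})
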