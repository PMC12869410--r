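#' Project a GMM to a Fourier half-plane image
#'
#' Analytic forward model: the mixture is rotated, its centres projected
#' along +z, and every Gaussian contributes
#' `amp * 2 pi sigma^2 * exp(-2 pi^2 sigma^2 |k|^2) *
#'  exp(-2 pi i k . (c_xy + shift))`
#' with `k` in cycles/box and positions in box units. This equals the
#' continuous 2-D Fourier transform of the projected image in the package
#' convention (see [fourier_from_image()]), so a unit Gaussian at the
#' origin has DC value `2 pi sigma^2`. The model is analytic in centres,
#' amplitudes and widths; gradients are provided internally for training.
#'
#' @param gmm A [gmm()] object.
#' @param rotation Unit quaternion `c(w, x, y, z)`.
#' @param shift In-plane shift in pixels (length 2), applied after
#'   rotation.
#' @param D Image size in pixels (even, >= 16).
#' @return `(D/2 + 1) x D` complex half-plane matrix.
#' @export
project_gmm <- function(gmm, rotation = c(1, 0, 0, 0), shift = c(0, 0),
                        D = 64) {
  stopifnot(D >= 16, D %% 2 == 0, length(shift) == 2)
  g <- freq_grid(D)
  R <- quat_to_matrix(rotation)
  mask <- list(idx = seq_along(g$kx), kx = as.vector(g$kx),
               ky = as.vector(g$ky), k2 = as.vector(g$k2), D = D)
  fw <- gmm_fourier(gmm$centers, gmm$amplitudes, gmm$widths, R,
                    shift, mask)
  matrix(fw$F, D / 2 + 1, D)
}

# Core analytic projection over an arbitrary frequency list.
# centers N x 3 (box units), amps N, widths N; Rmat 3x3; shift_px length 2;
# mask from ring_mask() (or a full-plane stand-in). Returns the complex
# coefficient vector and a cache for the reverse pass.
gmm_fourier <- function(centers, amps, widths, Rmat, shift_px, mask) {
  cxy <- centers %*% t(Rmat[1:2, , drop = FALSE])   # N x 2 projected
  sh <- shift_px / mask$D
  K <- cbind(mask$kx, mask$ky)                      # Nf x 2
  A <- K %*% t(cxy)                                 # Nf x N phase args
  A <- A + (mask$kx * sh[1] + mask$ky * sh[2])
  Ph <- exp(-2i * pi * A)
  Nf <- length(mask$k2)
  S <- exp(outer(mask$k2, -2 * pi^2 * widths^2))    # Nf x N envelope
  S <- S * rep(2 * pi * widths^2, each = Nf)
  Tm <- (S * rep(amps, each = Nf)) * Ph
  list(F = rowSums(Tm),
       cache = list(Tm = Tm, S = S, Ph = Ph, amps = amps, widths = widths,
                    Rmat = Rmat, mask = mask))
}

# Engine-dispatched projection used by the trainer: returns the complex
# coefficients and a closure computing parameter gradients from
# gbar = dL/dRe(F) + i dL/dIm(F).
project_particle <- function(centers, amps, widths, Rmat, shift_px, mask,
                             engine = ptgmm_engine()) {
  if (engine == "cpp") {
    cxy <- centers %*% t(Rmat[1:2, , drop = FALSE])
    sh <- shift_px / mask$D
    cxy[, 1] <- cxy[, 1] + sh[1]
    cxy[, 2] <- cxy[, 2] + sh[2]
    kxi <- as.integer(mask$kx); kyi <- as.integer(mask$ky)
    k2i <- as.integer(mask$k2)
    r <- proj_fwd_cpp(cxy, amps, widths, kxi, kyi, k2i)
    list(F = complex(real = r$re, imaginary = r$im),
         grad = function(gbar) {
           g <- proj_grad_cpp(cxy, amps, widths, kxi, kyi,
                              k2i, Re(gbar), Im(gbar))
           list(d_centers = g$dcxy %*% Rmat[1:2, , drop = FALSE],
                d_amps = g$damp, d_widths = g$dwid)
         })
  } else {
    fw <- gmm_fourier(centers, amps, widths, Rmat, shift_px, mask)
    list(F = fw$F,
         grad = function(gbar) gmm_fourier_grad(fw$cache, gbar))
  }
}

# Reverse pass of gmm_fourier. gbar = dL/dRe(F) + i dL/dIm(F) (length Nf).
# Returns gradients w.r.t. the unrotated 3D centers, amplitudes and widths.
gmm_fourier_grad <- function(cache, gbar) {
  m <- cache$mask
  M <- Conj(gbar) * cache$Tm                        # Nf x N
  ReM <- Re(M); ImM <- Im(M)
  d_amps <- Re(colSums(Conj(gbar) * (cache$S * cache$Ph)))
  dcx <- 2 * pi * colSums(ImM * m$kx)
  dcy <- 2 * pi * colSums(ImM * m$ky)
  d_cxy <- cbind(dcx, dcy)                          # grad w.r.t. rotated xy
  d_centers <- d_cxy %*% cache$Rmat[1:2, , drop = FALSE]
  sig <- cache$widths
  fac <- sweep(outer(m$k2, -4 * pi^2 * sig), 2, 2 / sig, `+`)
  d_widths <- colSums(ReM * fac)
  list(d_centers = d_centers, d_amps = d_amps, d_widths = d_widths)
}
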