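#' Naive direct-Fourier backprojection
#'
#' Reconstructs a 3-D volume from particle images by inserting each
#' image's Fourier half-plane into the rotated central slice of a 3-D
#' Fourier grid (nearest-voxel gridding, CTF phase flipping, count
#' normalisation) and inverting. This is the optional raw-particle route
#' for class difference maps; GMM-rendered volumes
#' ([class_difference_volume()]) are the default because at these scales
#' they are exact and fast.
#'
#' @param stack A particle stack (images + metadata).
#' @param particles Indices of the particles to use (default all).
#' @param max_ring Highest Fourier ring inserted (default Nyquist).
#' @return A D x D x D numeric array (arbitrary global scale).
#' @export
backproject_particles <- function(stack, particles = NULL,
                                  max_ring = NULL) {
  D <- stack$D
  if (is.null(particles)) particles <- seq_len(dim(stack$images)[3])
  if (is.null(max_ring)) max_ring <- D / 2 - 1
  md <- stack$metadata
  g <- freq_grid(D)
  keep <- which(g$ring <= max_ring)
  kx <- g$kx[keep]; ky <- g$ky[keep]
  Fvol <- array(0i, rep(D, 3))
  Wvol <- array(0, rep(D, 3))
  wrap <- function(k) ((round(k) %% D) + D) %% D + 1
  for (i in particles) {
    fh <- fourier_from_image(stack$images[, , i])
    ctf <- ctf_params(defocus = md$defocus[i], voltage = md$voltage[i],
                      cs = md$cs[i],
                      amplitude_contrast = md$amplitude_contrast[i],
                      b_factor = md$b_factor[i],
                      pixel_size = md$pixel_size[i])
    cv <- ctf_eval(ctf, g$k2, D)
    vals <- (fh * sign(cv))[keep]
    R <- euler_to_matrix(md$rot[i], md$tilt[i], md$psi[i])
    # a projection along z after rotation R samples the plane spanned by
    # the first two rows of R in reciprocal space
    K3 <- cbind(kx, ky) %*% R[1:2, , drop = FALSE]
    # insert both the slice and its Hermitian mate
    K3 <- rbind(K3, -K3)
    vals <- c(vals, Conj(vals))
    ix <- wrap(K3[, 1]); iy <- wrap(K3[, 2]); iz <- wrap(K3[, 3])
    lin <- ix + (iy - 1L) * D + (iz - 1L) * D * D
    agg <- rowsum(cbind(Re(vals), Im(vals), 1), lin)
    cells <- as.integer(rownames(agg))
    Fvol[cells] <- Fvol[cells] + complex(real = agg[, 1],
                                         imaginary = agg[, 2])
    Wvol[cells] <- Wvol[cells] + agg[, 3]
  }
  Fvol[Wvol > 0] <- Fvol[Wvol > 0] / Wvol[Wvol > 0]
  # undo the centring phase in all three axes and invert
  kxv <- c(0:(D / 2), (-D / 2 + 1):-1)
  ph1 <- exp(-1i * pi * kxv)
  phase <- outer(outer(ph1, ph1), ph1)
  vol <- Re(stats::fft(Fvol * phase, inverse = TRUE)) / D^3
  vol
}
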