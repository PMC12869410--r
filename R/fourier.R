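#' Fourier conventions
#'
#' Images are D x D real arrays with the particle centred at pixel
#' (D/2 + 1, D/2 + 1) (0-based D/2). Fourier images are stored as the
#' half-plane `(D/2 + 1) x D` complex matrix: row r holds kx = r - 1
#' (0 .. D/2 cycles/box), column c holds ky in FFT order
#' (0, 1, ..., D/2, -D/2 + 1, ..., -1). Values follow the continuous
#' transform of the centred image, so a unit-amplitude Gaussian of width
#' sigma (box units) at the origin has DC value 2 * pi * sigma^2 and no
#' phase. `fourier_from_image()` and `image_from_fourier()` convert
#' between the two representations, absorbing the centring phase and the
#' DFT scale.
#'
#' @name fourier-conventions
NULL

.grid_cache <- new.env(parent = emptyenv())

#' Half-plane frequency grid for a D x D image
#'
#' @param D Even image size in pixels.
#' @return List with matrices `kx`, `ky` (cycles/box), `k2` (= kx^2 + ky^2)
#'   and integer `ring` (= round(sqrt(k2))), each of dim `(D/2 + 1) x D`.
#' @export
freq_grid <- function(D) {
  key <- as.character(D)
  if (!is.null(.grid_cache[[key]])) return(.grid_cache[[key]])
  stopifnot(D %% 2 == 0, D >= 8)
  kx <- matrix(0:(D / 2), D / 2 + 1, D)
  kyv <- c(0:(D / 2), (-D / 2 + 1):-1)
  ky <- matrix(kyv, D / 2 + 1, D, byrow = TRUE)
  k2 <- kx^2 + ky^2
  g <- list(kx = kx, ky = ky, k2 = k2, ring = round(sqrt(k2)), D = D)
  .grid_cache[[key]] <- g
  g
}

#' Half-plane Fourier transform of a centred image
#'
#' @param img D x D real matrix.
#' @return `(D/2 + 1) x D` complex matrix in the package convention.
#' @export
fourier_from_image <- function(img) {
  D <- nrow(img)
  stopifnot(ncol(img) == D, D %% 2 == 0)
  g <- freq_grid(D)
  f <- stats::fft(img)[1:(D / 2 + 1), , drop = FALSE]
  f * exp(1i * pi * (g$kx + g$ky)) / D^2
}

#' Inverse of [fourier_from_image()]
#'
#' Fills the missing half-plane by Hermitian symmetry and returns the real
#' part of the inverse DFT.
#'
#' @param fh `(D/2 + 1) x D` complex half-plane.
#' @return D x D real matrix.
#' @export
image_from_fourier <- function(fh) {
  D <- ncol(fh)
  stopifnot(nrow(fh) == D / 2 + 1)
  g <- freq_grid(D)
  fh <- fh * exp(-1i * pi * (g$kx + g$ky)) * D^2
  full <- matrix(0i, D, D)
  full[1:(D / 2 + 1), ] <- fh
  # rows kx = -1 .. -(D/2 - 1) from conjugate symmetry F(-k) = conj(F(k))
  conj_col <- c(1L, D:2L)  # column index of -ky
  for (r in 2:(D / 2)) {
    full[D + 2 - r, ] <- Conj(fh[r, conj_col])
  }
  Re(stats::fft(full, inverse = TRUE)) / D^2
}

#' Ring-restricted frequency mask
#'
#' Indices (into the half-plane) of all frequencies with
#' `1 <= ring <= max_ring`, used to restrict the forward model and loss to
#' low resolution.
#'
#' @param D Image size; `max_ring` highest ring index kept.
#' @return List with integer vector `idx`, and `kx`, `ky`, `k2`, `ring`
#'   restricted to those entries.
#' @export
ring_mask <- function(D, max_ring) {
  g <- freq_grid(D)
  idx <- which(g$ring >= 1 & g$ring <= max_ring)
  list(idx = idx, kx = g$kx[idx], ky = g$ky[idx], k2 = g$k2[idx],
       ring = g$ring[idx], D = D, max_ring = max_ring)
}
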