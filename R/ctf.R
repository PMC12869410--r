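#' Contrast transfer function parameters
#'
#' Bundles microscope and per-particle CTF parameters. The sign convention
#' is the common single-particle one (underfocus positive, leading minus
#' sign): `CTF(g) = -(sqrt(1 - A^2) sin(chi) + A cos(chi)) * exp(-B g^2 / 4)`
#' with `chi(g) = pi * lambda * defocus * g^2 - (pi/2) * Cs * lambda^3 * g^4`
#' and `g` the spatial frequency in 1/Angstrom. The same function is used by
#' the simulator and the training forward model, so the convention cannot
#' drift between the two.
#'
#' @param defocus Defocus in micrometres (underfocus positive).
#' @param voltage Acceleration voltage in kV.
#' @param cs Spherical aberration in mm.
#' @param amplitude_contrast Amplitude contrast fraction in `[0, 1]`.
#' @param b_factor Envelope B-factor in Angstrom^2.
#' @param pixel_size Pixel size in Angstrom/pixel.
#' @return An object of class `ctf_params`.
#' @export
ctf_params <- function(defocus = 1.5, voltage = 300, cs = 2.7,
                       amplitude_contrast = 0.1, b_factor = 0,
                       pixel_size = 1) {
  stopifnot(pixel_size > 0, voltage > 0,
            amplitude_contrast >= 0, amplitude_contrast <= 1)
  structure(
    list(defocus = defocus, voltage = voltage, cs = cs,
         amplitude_contrast = amplitude_contrast, b_factor = b_factor,
         pixel_size = pixel_size),
    class = "ctf_params"
  )
}

electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1000
  12.2639 / sqrt(v + 0.97845e-6 * v^2)
}

#' Evaluate the CTF at given squared frequencies
#'
#' @param ctf A [ctf_params()] object.
#' @param k2 Squared frequency in (cycles/box)^2.
#' @param D Box size in pixels (converts cycles/box to 1/Angstrom via the
#'   pixel size).
#' @return Numeric CTF values, same shape as `k2`.
#' @export
ctf_eval <- function(ctf, k2, D) {
  g2 <- k2 / (D * ctf$pixel_size)^2
  lambda <- electron_wavelength(ctf$voltage)
  df_A <- ctf$defocus * 1e4
  cs_A <- ctf$cs * 1e7
  chi <- pi * lambda * df_A * g2 - (pi / 2) * cs_A * lambda^3 * g2^2
  a <- ctf$amplitude_contrast
  env <- exp(-ctf$b_factor * g2 / 4)
  -(sqrt(1 - a^2) * sin(chi) + a * cos(chi)) * env
}

#' Apply a CTF to a half-plane Fourier image
#'
#' @param fimage `(D/2 + 1) x D` complex half-plane (see
#'   [fourier_from_image()]).
#' @param ctf A [ctf_params()] object.
#' @return Fourier image multiplied by the CTF.
#' @export
ctf_apply <- function(fimage, ctf) {
  D <- ncol(fimage)
  g <- freq_grid(D)
  fimage * ctf_eval(ctf, g$k2, D)
}
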