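#' Particle encoder
#'
#' Maps a per-particle vector of Fourier coefficients (the phase-flipped
#' particle image below a resolution cutoff, real and imaginary parts
#' concatenated) to a d-dimensional latent code through a three-hidden-layer
#' MLP. In this family of models the encoder plays a smaller role than the
#' decoder; its width and the input cutoff are configuration values.
#'
#' @param input_dim Length of the encoder input vector.
#' @param latent_dim Latent dimension d.
#' @param hidden Hidden width.
#' @param seed Integer seed for initialisation.
#' @return An `encoder` object.
#' @export
init_encoder <- function(input_dim, latent_dim = 4, hidden = 256,
                         seed = 1) {
  set.seed(seed)
  params <- list(l1 = lin_init(input_dim, hidden),
                 l2 = lin_init(hidden, hidden),
                 l3 = lin_init(hidden, hidden),
                 out = lin_init(hidden, latent_dim, scale = 1 / sqrt(hidden)))
  structure(list(params = params, input_dim = input_dim,
                 latent_dim = latent_dim),
            class = "encoder")
}

enc_fwd <- function(X, p) {
  h1 <- relu(lin_fwd(X, p$l1))
  h2 <- relu(lin_fwd(h1, p$l2))
  h3 <- relu(lin_fwd(h2, p$l3))
  Z <- lin_fwd(h3, p$out)
  list(out = Z, cache = list(X = X, h1 = h1, h2 = h2, h3 = h3))
}

enc_bwd <- function(cache, p, dZ) {
  lo <- lin_bwd(cache$h3, p$out, dZ)
  d3 <- relu_bwd(cache$h3, lo$dX)
  l3 <- lin_bwd(cache$h2, p$l3, d3)
  d2 <- relu_bwd(cache$h2, l3$dX)
  l2 <- lin_bwd(cache$h1, p$l2, d2)
  d1 <- relu_bwd(cache$h1, l2$dX)
  l1 <- lin_bwd(cache$X, p$l1, d1)
  list(dX = l1$dX,
       grad = list(l1 = l1$grad, l2 = l2$grad, l3 = l3$grad,
                   out = lo$grad))
}

#' Encode particle inputs to latent codes
#'
#' @param input B x input_dim matrix (or a single vector).
#' @param encoder An [init_encoder()].
#' @return B x d latent matrix.
#' @export
encode <- function(input, encoder) {
  if (is.null(dim(input))) input <- matrix(input, 1)
  if (ncol(input) != encoder$input_dim) {
    stop(sprintf("encoder input length %d does not match configuration %d",
                 ncol(input), encoder$input_dim))
  }
  enc_fwd(input, encoder$params)$out
}

#' MLP decoder baseline
#'
#' The comparison decoder: a plain MLP from the latent code to N x 5
#' deltas with the same bounded output activations as the PT decoder, so
#' comparisons between the two isolate the architecture.
#'
#' @param n_gaussians GMM size N.
#' @param config A [decoder_config()] (channels are ignored; `latent_dim`
#'   and the output scales are used).
#' @param hidden Hidden width; three hidden layers are used.
#' @param seed Integer seed.
#' @return An `mlp_decoder` object.
#' @export
init_mlp_decoder <- function(n_gaussians, config = decoder_config(),
                             hidden = 256, seed = 1) {
  set.seed(seed)
  params <- list(l1 = lin_init(config$latent_dim, hidden),
                 l2 = lin_init(hidden, hidden),
                 l3 = lin_init(hidden, hidden),
                 head = lin_init(hidden, n_gaussians * 5, scale = 1e-3))
  structure(list(params = params, config = config,
                 n_gaussians = n_gaussians),
            class = "mlp_decoder")
}

mlp_decode_fwd <- function(Z, decoder) {
  p <- decoder$params; cfg <- decoder$config
  N <- decoder$n_gaussians; B <- nrow(Z)
  h1 <- relu(lin_fwd(Z, p$l1))
  h2 <- relu(lin_fwd(h1, p$l2))
  h3 <- relu(lin_fwd(h2, p$l3))
  U <- lin_fwd(h3, p$head)                     # B x (N*5)
  tu <- tanh(U)
  A5 <- array(tu, c(B, N, 5))
  out <- list(d_center = A5[, , 1:3, drop = FALSE] * cfg$center_scale,
              d_amplitude = A5[, , 4] * cfg$amp_scale,
              d_sigma = A5[, , 5] * cfg$sigma_scale)
  dim(out$d_center) <- c(B, N, 3)
  if (is.null(dim(out$d_amplitude))) {
    out$d_amplitude <- matrix(out$d_amplitude, B, N)
    out$d_sigma <- matrix(out$d_sigma, B, N)
  }
  list(out = out, cache = list(Z = Z, h1 = h1, h2 = h2, h3 = h3, tu = tu,
                               B = B, N = N))
}

mlp_decode_bwd <- function(cache, decoder, dOut) {
  p <- decoder$params; cfg <- decoder$config
  B <- cache$B; N <- cache$N
  dA5 <- array(0, c(B, N, 5))
  dA5[, , 1:3] <- dOut$d_center * cfg$center_scale
  dA5[, , 4] <- dOut$d_amplitude * cfg$amp_scale
  dA5[, , 5] <- dOut$d_sigma * cfg$sigma_scale
  dtu <- matrix(dA5, B, N * 5)
  dU <- tanh_bwd(cache$tu, dtu)
  lh <- lin_bwd(cache$h3, p$head, dU)
  d3 <- relu_bwd(cache$h3, lh$dX)
  l3 <- lin_bwd(cache$h2, p$l3, d3)
  d2 <- relu_bwd(cache$h2, l3$dX)
  l2 <- lin_bwd(cache$h1, p$l2, d2)
  d1 <- relu_bwd(cache$h1, l2$dX)
  l1 <- lin_bwd(cache$Z, p$l1, d1)
  list(dZ = l1$dX,
       grad = list(l1 = l1$grad, l2 = l2$grad, l3 = l3$grad,
                   head = lh$grad))
}

#' Decode with the MLP baseline
#'
#' @param latent Length-d vector or B x d matrix.
#' @param decoder An [init_mlp_decoder()].
#' @return A `decoder_output` with the same shapes as [decode()].
#' @export
mlp_decode <- function(latent, decoder) {
  if (is.null(dim(latent))) latent <- matrix(latent, 1)
  structure(mlp_decode_fwd(latent, decoder)$out, class = "decoder_output")
}

# Dispatch used by the trainer so PT and MLP decoders are plug-compatible.
net_decode_fwd <- function(Z, decoder, hierarchy) {
  if (inherits(decoder, "pt_decoder")) decode_fwd(Z, decoder, hierarchy)
  else mlp_decode_fwd(Z, decoder)
}

net_decode_bwd <- function(cache, decoder, hierarchy, dOut) {
  if (inherits(decoder, "pt_decoder")) {
    decode_bwd(cache, decoder, hierarchy, dOut)
  } else {
    mlp_decode_bwd(cache, decoder, dOut)
  }
}
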