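#' Training configuration
#'
#' Hyperparameters for unsupervised training of encoder + decoder against
#' particle images. All randomness (initialisation, shuffling) flows from
#' the single `seed`.
#'
#' @param epochs Training epochs.
#' @param batch_size Particles per batch.
#' @param lr Adam learning rate (cosine-decayed to 0 over training).
#' @param max_ring Highest Fourier ring used by the FRC loss (cycles/box).
#' @param enc_max_ring Highest ring of the encoder input; the spatial
#'   cutoff of the phase-flipped coefficients fed to the encoder.
#' @param enc_hidden Encoder hidden width.
#' @param amp_phase_epochs Optional first phase during which only the
#'   amplitude channel receives gradients (0 = off).
#' @param delta_l2 L2 penalty weight on the positional and width deltas
#'   (`delta_l2 * mean(d_center^2 + d_sigma^2)` added to the loss),
#'   shrinking unsupported deviations back to the neutral model; 0
#'   disables it.
#' @param seed Integer seed.
#' @return List of training settings.
#' @export
train_config <- function(epochs = 10, batch_size = 32, lr = 1e-3,
                         max_ring = NULL, enc_max_ring = NULL,
                         enc_hidden = 256, amp_phase_epochs = 0,
                         delta_l2 = 0, seed = 1) {
  list(epochs = epochs, batch_size = batch_size, lr = lr,
       max_ring = max_ring, enc_max_ring = enc_max_ring,
       enc_hidden = enc_hidden, amp_phase_epochs = amp_phase_epochs,
       delta_l2 = delta_l2, seed = seed)
}

# Precompute everything the loss needs per particle: masked observed
# Fourier coefficients, CTF values, rotation matrices, shifts, and the
# encoder input matrix (phase-flipped low-frequency coefficients).
prepare_particle_data <- function(stack, max_ring, enc_max_ring) {
  D <- stack$D
  n <- dim(stack$images)[3]
  if (is.null(max_ring)) max_ring <- round(D / 3)
  if (is.null(enc_max_ring)) enc_max_ring <- round(D / 4)
  mask <- ring_mask(D, max_ring)
  emask <- ring_mask(D, enc_max_ring)
  Nf <- length(mask$idx)
  md <- stack$metadata
  F_obs <- matrix(0i, n, Nf)
  E_in <- matrix(0, n, 2 * length(emask$idx))
  ctfv <- matrix(0, n, Nf)
  Rmats <- vector("list", n)
  lambda_chk <- NULL
  for (i in seq_len(n)) {
    fh <- fourier_from_image(stack$images[, , i])
    F_obs[i, ] <- fh[mask$idx]
    ctf <- ctf_params(defocus = md$defocus[i], voltage = md$voltage[i],
                      cs = md$cs[i],
                      amplitude_contrast = md$amplitude_contrast[i],
                      b_factor = md$b_factor[i],
                      pixel_size = md$pixel_size[i])
    ctfv[i, ] <- ctf_eval(ctf, mask$k2, D)
    ce <- ctf_eval(ctf, emask$k2, D)
    fe <- fh[emask$idx] * sign(ce)
    E_in[i, ] <- c(Re(fe), Im(fe))
    Rmats[[i]] <- quat_to_matrix(euler_to_quat(md$rot[i], md$tilt[i],
                                               md$psi[i]))
  }
  esc <- stats::sd(E_in)
  if (esc > 0) E_in <- E_in / esc
  list(F_obs = F_obs, ctfv = ctfv, E_in = E_in, Rmats = Rmats,
       shifts = cbind(md$shift_x, md$shift_y), mask = mask,
       enc_scale = esc, D = D, n = n, max_ring = max_ring,
       enc_max_ring = enc_max_ring)
}

#' Train a heterogeneity model on a particle stack
#'
#' Minimizes the mean FRC loss between each observed particle and the
#' CTF-modulated projection of the neutral GMM deformed by the decoded
#' per-particle deltas, by Adam over encoder and decoder weights.
#' Orientations and CTF parameters come from the stack metadata (they are
#' treated as known). Fully reproducible given the seed.
#'
#' @param stack A [render_particles()] stack (or compatible object with
#'   `images`, `metadata`, `D`).
#' @param neutral The neutral [gmm()].
#' @param decoder_type `"pt"` (point-transformer) or `"mlp"` baseline.
#' @param model_config A [decoder_config()].
#' @param config A [train_config()].
#' @param level_sizes,k_attn Hierarchy settings (PT decoder only).
#' @param mlp_hidden Hidden width of the MLP baseline.
#' @param verbose Print per-epoch loss.
#' @return A `ptgmm_model` with the trained weights, the hierarchy, the
#'   neutral GMM, and a per-batch `loss_trace` tibble.
#' @export
train_heterogeneity <- function(stack, neutral, decoder_type = c("pt", "mlp"),
                                model_config = decoder_config(),
                                config = train_config(),
                                level_sizes = NULL, k_attn = 16,
                                mlp_hidden = 256, verbose = FALSE) {
  decoder_type <- match.arg(decoder_type)
  N <- nrow(neutral$centers)
  prep <- prepare_particle_data(stack, config$max_ring,
                                config$enc_max_ring)
  hierarchy <- NULL
  if (decoder_type == "pt") {
    if (is.null(level_sizes)) {
      level_sizes <- unique(pmin(c(64, 256, N), N))
      if (length(level_sizes) < 3) level_sizes <- unique(c(
        max(4, N %/% 8), max(8, N %/% 3), N))
    }
    hierarchy <- build_hierarchy(neutral$centers, level_sizes,
                                 k_attn = k_attn, seed = config$seed)
    decoder <- init_pt_decoder(hierarchy, model_config,
                               seed = config$seed + 1)
    decoder$.geoms <- lapply(seq_along(hierarchy$level_sizes), function(l) {
      block_geom(hierarchy$level_points[[l]], hierarchy$neighbor_idx[[l]])
    })
  } else {
    decoder <- init_mlp_decoder(N, model_config, hidden = mlp_hidden,
                                seed = config$seed + 1)
  }
  encoder <- init_encoder(ncol(prep$E_in), model_config$latent_dim,
                          hidden = config$enc_hidden,
                          seed = config$seed + 2)
  params <- list(enc = encoder$params, dec = decoder$params)
  astate <- adam_init(params)
  n <- prep$n
  B <- config$batch_size
  n_batches <- ceiling(n / B)
  total_steps <- config$epochs * n_batches
  trace <- vector("list", total_steps)
  step <- 0
  gmax <- model_config$gate_max
  set.seed(config$seed + 3)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n)
    amp_only <- epoch <= config$amp_phase_epochs
    ep_loss <- 0
    for (bi in seq_len(n_batches)) {
      rows <- ord[((bi - 1) * B + 1):min(bi * B, n)]
      Bc <- length(rows)
      encoder$params <- params$enc
      decoder$params <- params$dec
      ef <- enc_fwd(prep$E_in[rows, , drop = FALSE], params$enc)
      df <- net_decode_fwd(ef$out, decoder, hierarchy)
      out <- df$out
      gate <- pmin(pmax(1 + out$d_amplitude, 0), gmax)
      sig_fac <- exp(pmin(pmax(out$d_sigma, -2), 2))
      dDC <- array(0, c(Bc, N, 3))
      dDA <- matrix(0, Bc, N)
      dDS <- matrix(0, Bc, N)
      loss <- 0
      for (b in seq_len(Bc)) {
        i <- rows[b]
        centers_p <- neutral$centers + out$d_center[b, , ]
        amps_p <- neutral$amplitudes * gate[b, ]
        widths_p <- neutral$widths * sig_fac[b, ]
        fw <- project_particle(centers_p, amps_p, widths_p,
                               prep$Rmats[[i]], prep$shifts[i, ],
                               prep$mask)
        P <- fw$F * prep$ctfv[i, ]
        fl <- frc_loss_masked(P, prep$F_obs[i, ], prep$mask$ring)
        loss <- loss + fl$loss / Bc
        gbar <- fl$grad() * prep$ctfv[i, ]
        gr <- fw$grad(gbar)
        dDC[b, , ] <- gr$d_centers / Bc
        open_gate <- (1 + out$d_amplitude[b, ] > 0) &
          (1 + out$d_amplitude[b, ] < gmax)
        dDA[b, ] <- gr$d_amps * neutral$amplitudes * open_gate / Bc
        in_rng <- abs(out$d_sigma[b, ]) < 2
        dDS[b, ] <- gr$d_widths * widths_p * in_rng / Bc
      }
      l2 <- config$delta_l2
      if (is.null(l2)) l2 <- 0
      if (l2 > 0) {
        loss <- loss + l2 * (mean(out$d_center^2) + mean(out$d_sigma^2))
        dDC <- dDC + 2 * l2 * out$d_center / length(out$d_center)
        dDS <- dDS + 2 * l2 * out$d_sigma / length(out$d_sigma)
      }
      if (!is.finite(loss)) {
        stop(sprintf("NaN/Inf loss at epoch %d batch %d; aborting",
                     epoch, bi))
      }
      if (amp_only) {
        dDC[] <- 0
        dDS[] <- 0
      }
      db <- net_decode_bwd(df$cache, decoder, hierarchy,
                           list(d_center = dDC, d_amplitude = dDA,
                                d_sigma = dDS))
      eb <- enc_bwd(ef$cache, params$enc, db$dZ)
      grads <- list(enc = eb$grad, dec = db$grad)
      step <- step + 1
      lr_t <- config$lr * 0.5 * (1 + cos(pi * (step - 1) / total_steps))
      upd <- adam_step(params, grads, astate, lr = lr_t)
      params <- upd$params
      astate <- upd$state
      ep_loss <- ep_loss + loss / n_batches
      trace[[step]] <- tibble::tibble(epoch = epoch, batch = bi,
                                      loss = loss, lr = lr_t)
    }
    if (verbose) {
      message(sprintf("epoch %d/%d  mean loss %.4f", epoch,
                      config$epochs, ep_loss))
    }
  }
  encoder$params <- params$enc
  decoder$params <- params$dec
  decoder$.geoms <- NULL
  structure(list(encoder = encoder, decoder = decoder,
                 decoder_type = decoder_type, hierarchy = hierarchy,
                 neutral = neutral, model_config = model_config,
                 train_config = config,
                 prep_config = list(D = prep$D, max_ring = prep$max_ring,
                                    enc_max_ring = prep$enc_max_ring,
                                    enc_scale = prep$enc_scale,
                                    n_train = n),
                 loss_trace = dplyr::bind_rows(trace)),
            class = "ptgmm_model")
}

#' @export
print.ptgmm_model <- function(x, ...) {
  cat(sprintf("<ptgmm_model> %s decoder, %d Gaussians, latent %d, %d epochs, final loss %.4f\n",
              x$decoder_type, nrow(x$neutral$centers),
              x$model_config$latent_dim,
              max(x$loss_trace$epoch), mean(tail(x$loss_trace$loss, 10))))
  invisible(x)
}

#' @export
glance.ptgmm_model <- function(x, ...) {
  tibble::tibble(
    decoder = x$decoder_type,
    n_gaussians = nrow(x$neutral$centers),
    latent_dim = x$model_config$latent_dim,
    n_parameters = param_count(x$decoder$params) +
      param_count(x$encoder$params),
    epochs = max(x$loss_trace$epoch),
    initial_loss = mean(head(x$loss_trace$loss, 5)),
    final_loss = mean(tail(x$loss_trace$loss, 5)))
}

#' @export
tidy.ptgmm_model <- function(x, ...) x$loss_trace

#' Run inference on a particle stack
#'
#' Deterministic forward pass of the trained encoder + decoder over every
#' particle.
#'
#' @param model A trained [train_heterogeneity()] model.
#' @param stack A particle stack with the same image size and metadata
#'   columns as the training stack.
#' @param batch_size Particles per forward batch.
#' @return A `ptgmm_particles` object: `latent` (n x d), `d_center`
#'   (n x N x 3), `d_amplitude`, `d_sigma`, `gate` (n x N each).
#' @export
infer <- function(model, stack, batch_size = 64) {
  if (stack$D != model$prep_config$D) {
    stop("stack image size does not match the trained model configuration")
  }
  prep <- prepare_particle_data(stack, model$prep_config$max_ring,
                                model$prep_config$enc_max_ring)
  E_in <- prep$E_in * prep$enc_scale / model$prep_config$enc_scale
  n <- prep$n
  N <- nrow(model$neutral$centers)
  d <- model$model_config$latent_dim
  latent <- matrix(0, n, d)
  dc <- array(0, c(n, N, 3))
  da <- matrix(0, n, N)
  ds <- matrix(0, n, N)
  decoder <- model$decoder
  if (model$decoder_type == "pt") {
    decoder$.geoms <- lapply(seq_along(model$hierarchy$level_sizes),
                             function(l) {
      block_geom(model$hierarchy$level_points[[l]],
                 model$hierarchy$neighbor_idx[[l]])
    })
  }
  for (s in seq(1, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1)
    Z <- enc_fwd(E_in[s:e, , drop = FALSE], model$encoder$params)$out
    out <- net_decode_fwd(Z, decoder, model$hierarchy)$out
    latent[s:e, ] <- Z
    dc[s:e, , ] <- out$d_center
    da[s:e, ] <- out$d_amplitude
    ds[s:e, ] <- out$d_sigma
  }
  structure(list(latent = latent, d_center = dc, d_amplitude = da,
                 d_sigma = ds,
                 gate = amplitude_gate(da, model$model_config$gate_max),
                 neutral = model$neutral,
                 box_size_A = stack$pixel_size * stack$D,
                 decoder_type = model$decoder_type),
            class = "ptgmm_particles")
}

#' @export
print.ptgmm_particles <- function(x, ...) {
  cat(sprintf("<ptgmm_particles> %d particles x %d Gaussians (%s decoder)\n",
              nrow(x$latent), ncol(x$gate), x$decoder_type))
  invisible(x)
}

#' @export
tidy.ptgmm_particles <- function(x, ...) {
  n <- nrow(x$latent); N <- ncol(x$gate)
  tibble::tibble(
    particle = rep(seq_len(n), each = N),
    gaussian = rep(seq_len(N), times = n),
    dx = as.vector(t(x$d_center[, , 1])),
    dy = as.vector(t(x$d_center[, , 2])),
    dz = as.vector(t(x$d_center[, , 3])),
    amplitude = as.vector(t(x$gate)),
    d_sigma = as.vector(t(x$d_sigma)))
}
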