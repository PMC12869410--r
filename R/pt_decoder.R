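#' Point-transformer decoder
#'
#' The decoder maps a low-dimensional latent conformation code to
#' per-Gaussian changes of the neutral GMM (Delta-centre, Delta-amplitude,
#' Delta-sigma). A two-layer MLP seeds features onto the coarsest level of
#' the precomputed point hierarchy; each level applies vector
#' self-attention over k nearest neighbours with a learned relative
#' position encoding, and features are upsampled between levels by
#' inverse-distance transition-up. Residual branches upsample the first
#' two levels' outputs directly to the full GMM; their features are
#' concatenated with the final level's output and passed through a
#' pointwise dense head whose five channels (Delta-xyz, Delta-amplitude,
#' Delta-sigma) are bounded by scaled tanh activations.
#'
#' @name pt-decoder
NULL

#' Decoder configuration
#'
#' @param channels Feature channels per hierarchy level (coarse to fine).
#' @param latent_dim Latent code dimension.
#' @param seed_hidden Hidden width of the latent-seed MLP.
#' @param pos_hidden Hidden width of the position-encoding MLP.
#' @param resid_channels Width of each residual branch after projection.
#' @param center_scale Bound (box units) of the Delta-centre tanh.
#' @param amp_scale Bound of the raw Delta-amplitude tanh (the gate applied
#'   by [apply_deltas()] is `clamp(1 + d_amplitude, 0, gate_max)`).
#' @param sigma_scale Bound of the Delta-log-sigma tanh.
#' @param gate_max Upper bound of the amplitude gate.
#' @return A list of configuration values.
#' @export
decoder_config <- function(channels = c(256, 128, 64), latent_dim = 4,
                           seed_hidden = 128, pos_hidden = 16,
                           resid_channels = 32, center_scale = 0.1,
                           amp_scale = 1.5, sigma_scale = 0.5,
                           gate_max = 2) {
  list(channels = channels, latent_dim = latent_dim,
       seed_hidden = seed_hidden, pos_hidden = pos_hidden,
       resid_channels = resid_channels, center_scale = center_scale,
       amp_scale = amp_scale, sigma_scale = sigma_scale,
       gate_max = gate_max)
}

#' Initialise attention-block weights
#'
#' @param C Channel width of the block.
#' @param pos_hidden Hidden width of the position-encoding MLP.
#' @return Named list of linear-layer parameters.
#' @export
pt_block_weights <- function(C, pos_hidden = 16) {
  list(phi = lin_init(C, C), psi = lin_init(C, C), alpha = lin_init(C, C),
       theta1 = lin_init(3, pos_hidden), theta2 = lin_init(pos_hidden, C),
       gamma1 = lin_init(C, C), gamma2 = lin_init(C, C, scale = 1 / sqrt(C)),
       out = lin_init(C, C, scale = 1 / sqrt(C)))
}

#' Initialise a full PT decoder for a hierarchy
#'
#' @param hierarchy A [build_hierarchy()] object.
#' @param config A [decoder_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A `pt_decoder` object (weights + config).
#' @export
init_pt_decoder <- function(hierarchy, config = decoder_config(), seed = 1) {
  L <- length(hierarchy$level_sizes)
  stopifnot(length(config$channels) == L)
  set.seed(seed)
  ch <- config$channels
  params <- list(
    seed = list(l1 = lin_init(config$latent_dim, config$seed_hidden),
                l2 = lin_init(config$seed_hidden,
                              hierarchy$level_sizes[1] * ch[1]))
  )
  params$blocks <- lapply(seq_len(L), function(l) {
    pt_block_weights(ch[l], config$pos_hidden)
  })
  if (L > 1) {
    params$trans <- lapply(seq_len(L - 1), function(l) {
      lin_init(ch[l], ch[l + 1])
    })
  }
  r <- config$resid_channels
  head_in <- ch[L]
  if (L > 2) {
    params$resid <- lapply(seq_len(L - 1), function(l) lin_init(ch[l], r))
    head_in <- head_in + (L - 1) * r
  }
  params$head <- lin_init(head_in, 5, scale = 1e-3)
  structure(list(params = params, config = config,
                 level_sizes = hierarchy$level_sizes),
            class = "pt_decoder")
}

# --- geometry caches ------------------------------------------------------

# Per-level static geometry used by the attention block.
block_geom <- function(points, nbr) {
  P <- nrow(points); k <- ncol(nbr)
  nbr_base <- as.vector(t(nbr))               # length P*k, neighbour-fastest
  ctr_base <- rep(seq_len(P), each = k)
  rel <- points[ctr_base, , drop = FALSE] - points[nbr_base, , drop = FALSE]
  list(P = P, k = k, nbr_base = nbr_base, ctr_base = ctr_base, rel = rel,
       nbr0 = matrix(as.integer(nbr - 1L), P, k))
}

# Computation engine for the decoder and forward model: the compiled
# kernels ("cpp", default) or the plain-R reference path ("r").
ptgmm_engine <- function() getOption("ptgmm.engine", "cpp")

batch_expand <- function(base, P, B) {
  rep(base, times = B) + rep((0:(B - 1)) * P, each = length(base))
}

scatter_rows <- function(dG, idx, n) {
  out <- matrix(0, n, ncol(dG))
  rs <- rowsum(dG, idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# Channel-wise softmax over neighbour groups. `sc` is a (BPk) x C matrix
# whose rows are neighbour-fastest; its column-major layout lets us view
# it as k x (BP*C) without copying the data.
softmax_k <- function(sc, k) {
  nr <- nrow(sc); nc <- ncol(sc)
  dim(sc) <- c(k, (nr / k) * nc)
  mx <- sc[1, ]
  if (k > 1) for (j in 2:k) mx <- pmax(mx, sc[j, ])
  E <- exp(sc - rep(mx, each = k))
  S <- colSums(E)
  A <- E / rep(S, each = k)
  dim(A) <- c(nr, nc)
  A
}

# --- attention block ------------------------------------------------------

pt_block_fwd <- function(X, p, geom, B, engine = ptgmm_engine()) {
  if (engine == "cpp") {
    r <- attn_fwd_cpp(X, p$phi$W, p$phi$b, p$psi$W, p$psi$b,
                      p$alpha$W, p$alpha$b, p$theta1$W, p$theta1$b,
                      p$theta2$W, p$theta2$b, p$gamma1$W, p$gamma1$b,
                      p$gamma2$W, p$gamma2$b, p$out$W, p$out$b,
                      geom$rel, geom$nbr0, B)
    return(list(out = r$out,
                cache = list(cpp = r$cache, geom = geom, B = B,
                             engine = "cpp")))
  }
  P <- geom$P; k <- geom$k; C <- ncol(X)
  nbr_flat <- batch_expand(geom$nbr_base, P, B)
  ctr_flat <- batch_expand(geom$ctr_base, P, B)
  q <- lin_fwd(X, p$phi); kk <- lin_fwd(X, p$psi); v <- lin_fwd(X, p$alpha)
  h1 <- relu(lin_fwd(geom$rel, p$theta1))
  dd <- lin_fwd(h1, p$theta2)                 # (P*k) x C
  tI <- rep(seq_len(P * k), times = B)
  dE <- dd[tI, , drop = FALSE]
  s <- q[ctr_flat, , drop = FALSE] - kk[nbr_flat, , drop = FALSE] + dE
  g1 <- relu(lin_fwd(s, p$gamma1))
  sc <- lin_fwd(g1, p$gamma2)
  A <- softmax_k(sc, k)
  gv <- v[nbr_flat, , drop = FALSE] + dE
  w <- A * gv
  dim(w) <- c(k, B * P * C)
  y <- colSums(w)
  dim(y) <- c(B * P, C)
  o <- lin_fwd(y, p$out)
  list(out = X + o,
       cache = list(X = X, q = q, kk = kk, v = v, h1 = h1, s = s,
                    g1 = g1, A = A, gv = gv, y = y,
                    nbr_flat = nbr_flat, ctr_flat = ctr_flat, tI = tI,
                    geom = geom, B = B))
}

pt_block_bwd <- function(cache, p, dOut) {
  if (identical(cache$engine, "cpp")) {
    r <- attn_bwd_cpp(cache$cpp,
                      p$phi$W, p$psi$W, p$alpha$W, p$theta1$W, p$theta2$W,
                      p$gamma1$W, p$gamma2$W, p$out$W,
                      cache$geom$rel, cache$geom$nbr0, cache$B, dOut)
    gr <- r[c("phi", "psi", "alpha", "theta1", "theta2", "gamma1",
              "gamma2", "out")]
    gr <- lapply(gr, function(g) list(W = g$W, b = as.numeric(g$b)))
    return(list(dX = r$dX, grad = gr))
  }
  ge <- cache$geom; P <- ge$P; k <- ge$k; B <- cache$B
  BP <- B * P; C <- ncol(dOut)
  lo <- lin_bwd(cache$y, p$out, dOut)
  dy <- lo$dX
  grp <- rep(seq_len(BP), each = k)
  dw <- dy[grp, , drop = FALSE]
  dA <- dw * cache$gv
  dgv <- dw * cache$A
  # softmax backward over neighbour groups (zero-copy k-view reshape)
  Ak <- cache$A
  dim(Ak) <- c(k, BP * C)
  dim(dA) <- c(k, BP * C)
  Tk <- colSums(Ak * dA)
  dsc <- Ak * (dA - rep(Tk, each = k))
  dim(dsc) <- c(BP * k, C)
  lg2 <- lin_bwd(cache$g1, p$gamma2, dsc)
  dg1 <- relu_bwd(cache$g1, lg2$dX)
  lg1 <- lin_bwd(cache$s, p$gamma1, dg1)
  ds <- lg1$dX
  dq_g <- ds
  dk_g <- -ds
  ddE <- dgv + ds
  # collapse batch tiles onto the (P*k) position-encoding rows
  ddd <- rowsum(ddE, cache$tI)
  lt2 <- lin_bwd(cache$h1, p$theta2, ddd)
  dh1 <- relu_bwd(cache$h1, lt2$dX)
  lt1 <- lin_bwd(ge$rel, p$theta1, dh1)
  dq <- scatter_rows(dq_g, cache$ctr_flat, BP)
  dkk <- scatter_rows(dk_g, cache$nbr_flat, BP)
  dv <- scatter_rows(dgv, cache$nbr_flat, BP)
  lphi <- lin_bwd(cache$X, p$phi, dq)
  lpsi <- lin_bwd(cache$X, p$psi, dkk)
  lalp <- lin_bwd(cache$X, p$alpha, dv)
  dX <- dOut + lphi$dX + lpsi$dX + lalp$dX
  list(dX = dX,
       grad = list(phi = lphi$grad, psi = lpsi$grad, alpha = lalp$grad,
                   theta1 = lt1$grad, theta2 = lt2$grad,
                   gamma1 = lg1$grad, gamma2 = lg2$grad, out = lo$grad))
}

#' Vector self-attention block (functional form)
#'
#' One PT block applied to a point set: for each point, attention over its
#' k stored neighbours with scores `gamma(phi(x_i) - psi(x_j) + delta_ij)`
#' softmaxed channel-wise over j, values `alpha(x_j) + delta_ij`, position
#' encoding `delta_ij = theta(p_i - p_j)`, and a residual connection.
#'
#' @param features `(B*P) x C` feature matrix (point index fastest).
#' @param points P x 3 point positions.
#' @param neighbor_idx P x k integer neighbour table.
#' @param weights From [pt_block_weights()].
#' @param batch Batch size B.
#' @return `(B*P) x C` output features.
#' @export
pt_block <- function(features, points, neighbor_idx, weights, batch = 1) {
  geom <- block_geom(points, neighbor_idx)
  pt_block_fwd(features, weights, geom, batch)$out
}

# --- transition up --------------------------------------------------------

tup_fwd <- function(Xc, p, tab, B, P1) {
  P2 <- nrow(tab$idx); ni <- ncol(tab$idx)
  proj <- lin_fwd(Xc, p)
  idx_base <- as.vector(t(tab$idx))
  w_flat <- rep(as.vector(t(tab$weight)), times = B)
  flat <- batch_expand(idx_base, P1, B)
  gathered <- proj[flat, , drop = FALSE] * w_flat
  Cp <- ncol(proj)
  dim(gathered) <- c(ni, B * P2 * Cp)
  y <- colSums(gathered)
  dim(y) <- c(B * P2, Cp)
  list(out = y, cache = list(Xc = Xc, proj = proj, flat = flat,
                             w_flat = w_flat, ni = ni, B = B, P1 = P1,
                             P2 = P2))
}

tup_bwd <- function(cache, p, dY) {
  grp <- rep(seq_len(cache$B * cache$P2), each = cache$ni)
  dg <- dY[grp, , drop = FALSE] * cache$w_flat
  dproj <- scatter_rows(dg, cache$flat, cache$B * cache$P1)
  lb <- lin_bwd(cache$Xc, p, dproj)
  list(dX = lb$dX, grad = lb$grad)
}

#' Transition-up feature interpolation (functional form)
#'
#' Each fine point's feature is the inverse-distance-weighted sum of its 3
#' nearest coarse points' linearly projected features.
#'
#' @param coarse_feat `(B*P1) x C1` coarse features.
#' @param up_idx,up_weight Interpolation tables from [build_hierarchy()].
#' @param weights Linear projection parameters (`list(W, b)`).
#' @param batch Batch size.
#' @return `(B*P2) x C2` fine features.
#' @export
transition_up <- function(coarse_feat, up_idx, up_weight, weights,
                          batch = 1) {
  P1 <- nrow(coarse_feat) / batch
  tup_fwd(coarse_feat, weights, list(idx = up_idx, weight = up_weight),
          batch, P1)$out
}

# --- latent seed ----------------------------------------------------------

seed_fwd <- function(Z, p, P1, C1) {
  B <- nrow(Z)
  h <- relu(lin_fwd(Z, p$l1))
  H <- lin_fwd(h, p$l2)                        # B x (P1*C1)
  X <- matrix(aperm(array(H, c(B, P1, C1)), c(2, 1, 3)), B * P1, C1)
  list(out = X, cache = list(Z = Z, h = h, B = B, P1 = P1, C1 = C1))
}

seed_bwd <- function(cache, p, dX) {
  B <- cache$B; P1 <- cache$P1; C1 <- cache$C1
  dH <- matrix(aperm(array(dX, c(P1, B, C1)), c(2, 1, 3)), B, P1 * C1)
  l2 <- lin_bwd(cache$h, p$l2, dH)
  dh <- relu_bwd(cache$h, l2$dX)
  l1 <- lin_bwd(cache$Z, p$l1, dh)
  list(dZ = l1$dX, grad = list(l1 = l1$grad, l2 = l2$grad))
}

#' Seed decoder features from a latent code
#'
#' Two-layer MLP mapping the latent vector to a `(B, P1, C)` feature
#' tensor assigned to the coarsest hierarchy level.
#'
#' @param latent B x d latent matrix (or length-d vector).
#' @param weights `list(l1, l2)` linear parameters.
#' @param n_points,channels Coarse level size and channel width.
#' @return `(B*P1) x C` feature matrix.
#' @export
latent_seed <- function(latent, weights, n_points = 64, channels = 256) {
  if (is.null(dim(latent))) latent <- matrix(latent, 1)
  seed_fwd(latent, weights, n_points, channels)$out
}

# --- full decode ----------------------------------------------------------

decode_fwd <- function(Z, decoder, hierarchy) {
  cfg <- decoder$config; p <- decoder$params
  L <- length(hierarchy$level_sizes)
  B <- nrow(Z)
  geoms <- decoder$.geoms
  if (is.null(geoms)) {
    geoms <- lapply(seq_len(L), function(l) {
      block_geom(hierarchy$level_points[[l]], hierarchy$neighbor_idx[[l]])
    })
  }
  caches <- list()
  sf <- seed_fwd(Z, p$seed, hierarchy$level_sizes[1], cfg$channels[1])
  caches$seed <- sf$cache
  X <- sf$out
  lvl_out <- vector("list", L)
  caches$blocks <- vector("list", L)
  caches$trans <- vector("list", max(L - 1, 0))
  for (l in seq_len(L)) {
    bf <- pt_block_fwd(X, p$blocks[[l]], geoms[[l]], B)
    caches$blocks[[l]] <- bf$cache
    lvl_out[[l]] <- bf$out
    if (l < L) {
      tf <- tup_fwd(bf$out, p$trans[[l]], hierarchy$up[[l]], B,
                    hierarchy$level_sizes[l])
      caches$trans[[l]] <- tf$cache
      X <- tf$out
    }
  }
  H <- lvl_out[[L]]
  caches$resid <- NULL
  if (L > 2) {
    caches$resid <- vector("list", L - 1)
    parts <- list(H)
    for (l in seq_len(L - 1)) {
      rf <- tup_fwd(lvl_out[[l]], p$resid[[l]], hierarchy$resid_up[[l]], B,
                    hierarchy$level_sizes[l])
      caches$resid[[l]] <- rf$cache
      parts[[l + 1]] <- rf$out
    }
    H <- do.call(cbind, parts)
  }
  U <- lin_fwd(H, p$head)                      # (B*N) x 5
  tu <- tanh(U)
  N <- hierarchy$level_sizes[L]
  # rows are point-fastest within batch: row = (b-1)*N + i
  dc <- aperm(array(tu[, 1:3], c(N, B, 3)), c(2, 1, 3)) * cfg$center_scale
  da <- t(matrix(tu[, 4], N, B)) * cfg$amp_scale
  dsg <- t(matrix(tu[, 5], N, B)) * cfg$sigma_scale
  list(out = list(d_center = dc, d_amplitude = da, d_sigma = dsg),
       cache = list(caches = caches, H = H, tu = tu, B = B, N = N, L = L))
}

decode_bwd <- function(cache, decoder, hierarchy, dOut) {
  cfg <- decoder$config; p <- decoder$params
  B <- cache$B; N <- cache$N; L <- cache$L
  dtu <- matrix(0, B * N, 5)
  dtu[, 1:3] <- matrix(aperm(dOut$d_center, c(2, 1, 3)), B * N, 3) *
    cfg$center_scale
  dtu[, 4] <- as.vector(t(dOut$d_amplitude)) * cfg$amp_scale
  dtu[, 5] <- as.vector(t(dOut$d_sigma)) * cfg$sigma_scale
  dU <- tanh_bwd(cache$tu, dtu)
  lh <- lin_bwd(cache$H, p$head, dU)
  grads <- list(head = lh$grad)
  dH <- lh$dX
  C_L <- cfg$channels[L]
  dXL <- dH[, 1:C_L, drop = FALSE]
  dlvl <- vector("list", L)
  dlvl[[L]] <- dXL
  if (L > 2) {
    grads$resid <- vector("list", L - 1)
    off <- C_L
    for (l in seq_len(L - 1)) {
      r <- cfg$resid_channels
      dR <- dH[, (off + 1):(off + r), drop = FALSE]
      off <- off + r
      rb <- tup_bwd(cache$caches$resid[[l]], p$resid[[l]], dR)
      grads$resid[[l]] <- rb$grad
      dlvl[[l]] <- rb$dX
    }
  }
  grads$blocks <- vector("list", L)
  if (L > 1) grads$trans <- vector("list", L - 1)
  dX <- dlvl[[L]]
  for (l in L:1) {
    bb <- pt_block_bwd(cache$caches$blocks[[l]], p$blocks[[l]], dX)
    grads$blocks[[l]] <- bb$grad
    dXin <- bb$dX
    if (l > 1) {
      tb <- tup_bwd(cache$caches$trans[[l - 1]], p$trans[[l - 1]], dXin)
      grads$trans[[l - 1]] <- tb$grad
      dX <- tb$dX
      if (!is.null(dlvl[[l - 1]])) dX <- dX + dlvl[[l - 1]]
    } else {
      sb <- seed_bwd(cache$caches$seed, p$seed, dXin)
      grads$seed <- sb$grad
      # mirror the parameter list ordering exactly
      grads <- grads[names(p)]
      return(list(dZ = sb$dZ, grad = grads))
    }
  }
}

#' Decode a latent code into per-Gaussian deltas
#'
#' Runs the full PT decoder pipeline (latent seed, per-level attention and
#' transition-up, residual branches, pointwise head) and returns a
#' `decoder_output`.
#'
#' @param latent Length-d vector or B x d matrix of latent codes.
#' @param hierarchy A [build_hierarchy()] for the neutral GMM.
#' @param decoder An [init_pt_decoder()] (its hierarchy sizes must match).
#' @return A `decoder_output`: list of `d_center` (B x N x 3, box units),
#'   `d_amplitude` (B x N, raw bounded gate input) and `d_sigma` (B x N,
#'   bounded log-width change).
#' @export
decode <- function(latent, hierarchy, decoder) {
  if (is.null(dim(latent))) latent <- matrix(latent, 1)
  if (!identical(decoder$level_sizes, hierarchy$level_sizes)) {
    stop("decoder and hierarchy level sizes disagree")
  }
  out <- decode_fwd(latent, decoder, hierarchy)$out
  structure(out, class = "decoder_output")
}

#' Apply decoded deltas to the neutral GMM
#'
#' Centres move by `d_center`; amplitudes are multiplied by the bounded
#' gate `clamp(1 + d_amplitude, 0, gate_max)`, which equals 1 at zero
#' delta and reaches exactly 0 at the gate floor (a fully absent
#' segment); widths are multiplied by `exp(d_sigma)`.
#'
#' @param neutral The neutral [gmm()].
#' @param delta A `decoder_output` for a single particle (or index `b` of
#'   a batched output).
#' @param b Batch row to apply (default 1).
#' @param gate_max Gate upper bound.
#' @return A [gmm()] for this particle.
#' @export
apply_deltas <- function(neutral, delta, b = 1, gate_max = 2) {
  N <- nrow(neutral$centers)
  dc <- delta$d_center
  if (length(dim(dc)) == 3) dc <- dc[b, , ]
  da <- delta$d_amplitude
  if (is.matrix(da)) da <- da[b, ]
  ds <- delta$d_sigma
  if (is.matrix(ds)) ds <- ds[b, ]
  stopifnot(nrow(dc) == N, length(da) == N, length(ds) == N)
  gate <- pmin(pmax(1 + da, 0), gate_max)
  gmm(neutral$centers + dc,
      neutral$amplitudes * gate,
      neutral$widths * exp(pmin(pmax(ds, -2), 2)))
}

#' Amplitude gate applied by [apply_deltas()]
#'
#' @param d_amplitude Raw amplitude deltas.
#' @param gate_max Upper bound.
#' @return Gate values in `[0, gate_max]`.
#' @export
amplitude_gate <- function(d_amplitude, gate_max = 2) {
  pmin(pmax(1 + d_amplitude, 0), gate_max)
}
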