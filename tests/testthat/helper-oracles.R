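# Independent brute-force oracles used across the test files. These are
# deliberately written as plain loops, separate from the package's
# vectorized / compiled implementations.

# Real-space rendering of the projected 2-D Gaussians of a gmm (identity
# frame handled by rotating coordinates first).
oracle_projection_image <- function(gmm, rotation, shift_px, D) {
  R <- quat_to_matrix(rotation)
  cxy <- gmm$centers %*% t(R[1:2, , drop = FALSE])
  cxy <- cxy + matrix(shift_px / D, nrow(cxy), 2, byrow = TRUE)
  ax <- ((0:(D - 1)) - D / 2) / D
  img <- matrix(0, D, D)
  for (i in seq_len(nrow(cxy))) {
    gx <- exp(-(ax - cxy[i, 1])^2 / (2 * gmm$widths[i]^2))
    gy <- exp(-(ax - cxy[i, 2])^2 / (2 * gmm$widths[i]^2))
    img <- img + gmm$amplitudes[i] * outer(gx, gy)
  }
  img
}

# Naive per-point, per-neighbour vector self-attention (single batch
# element at a time), mirroring the documented block definition.
oracle_pt_block <- function(X, points, nbr, w, B = 1) {
  P <- nrow(points); k <- ncol(nbr); C <- ncol(X)
  lin1 <- function(x, p) {
    if (is.null(dim(x))) x <- matrix(x, 1)
    x %*% p$W + matrix(p$b, nrow(x), length(p$b), byrow = TRUE)
  }
  out <- X * 0
  for (b in seq_len(B)) {
    rows <- (b - 1) * P + seq_len(P)
    Xb <- X[rows, , drop = FALSE]
    q <- lin1(Xb, w$phi); kk <- lin1(Xb, w$psi); v <- lin1(Xb, w$alpha)
    for (i in seq_len(P)) {
      scores <- matrix(0, k, C)
      vals <- matrix(0, k, C)
      for (j in seq_len(k)) {
        nj <- nbr[i, j]
        d <- points[i, ] - points[nj, ]
        h <- pmax(lin1(d, w$theta1), 0)
        dd <- lin1(h, w$theta2)
        s <- q[i, ] - kk[nj, ] + dd
        g <- lin1(pmax(lin1(s, w$gamma1), 0), w$gamma2)
        scores[j, ] <- g
        vals[j, ] <- v[nj, ] + dd
      }
      y <- numeric(C)
      for (c in seq_len(C)) {
        e <- exp(scores[, c] - max(scores[, c]))
        a <- e / sum(e)
        y[c] <- sum(a * vals[, c])
      }
      out[rows[i], ] <- Xb[i, ] + lin1(y, w$out)
    }
  }
  out
}

# Naive inverse-distance interpolation loop.
oracle_transition_up <- function(coarse_feat, up_idx, up_weight, w, B = 1) {
  P1 <- nrow(coarse_feat) / B
  proj <- coarse_feat %*% w$W +
    matrix(w$b, nrow(coarse_feat), length(w$b), byrow = TRUE)
  P2 <- nrow(up_idx)
  out <- matrix(0, B * P2, ncol(proj))
  for (b in seq_len(B)) {
    for (f in seq_len(P2)) {
      acc <- numeric(ncol(proj))
      for (t in seq_len(ncol(up_idx))) {
        acc <- acc + up_weight[f, t] * proj[(b - 1) * P1 + up_idx[f, t], ]
      }
      out[(b - 1) * P2 + f, ] <- acc
    }
  }
  out
}

# Brute-force nearest neighbour (lowest index wins ties).
oracle_nearest <- function(query, pts) {
  out <- integer(nrow(query))
  for (i in seq_len(nrow(query))) {
    d <- colSums((t(pts) - query[i, ])^2)
    out[i] <- which.min(d)
  }
  out
}

# Distance correlation (bias-uncorrected, O(n^2)) between two samples.
oracle_dcor <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  dc <- function(m) {
    d <- as.matrix(dist(m))
    d - outer(rowMeans(d), colMeans(d), `+`) + mean(d)
  }
  A <- dc(x); B <- dc(y)
  dcov2 <- mean(A * B)
  sqrt(dcov2 / sqrt(mean(A * A) * mean(B * B)))
}

# Small shared fixtures -----------------------------------------------------

tiny_structure <- function(seed = 1, n_segments = 5) {
  make_toy_structure(n_segments, pts_per_segment = 40, seed = seed)
}

tiny_gmm <- function(seed = 2) {
  set.seed(seed)
  gmm(matrix(runif(30, -0.3, 0.3), 10, 3), runif(10, 0.5, 1.5),
      runif(10, 0.02, 0.05))
}
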