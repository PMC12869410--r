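#' Seeded 2-D manifold embedding
#'
#' A compact UMAP-style embedding implemented in the package: a fuzzy
#' k-nearest-neighbour graph (local connectivity 1, smooth-kNN bandwidth
#' calibrated so each point's effective neighbour count is log2(k)),
#' symmetrized by fuzzy union, is laid out in 2-D by batch gradient
#' descent on the usual attraction/repulsion curve (`1 / (1 + a d^{2b})`,
#' fitted here for min_dist 0.1) with a linearly decaying step size.
#' Unlike sampling-based layouts, repulsion is evaluated over all pairs
#' (scaled to the equivalent negative-sampling budget), so the layout is
#' deterministic and equivariant under row permutation: two runs with one
#' seed agree exactly, and shuffling the rows shuffles the embedding.
#' Initialisation is the first two principal components with a
#' deterministic sign convention plus a tiny data-derived jitter.
#'
#' @param X n x F feature matrix (rows are embedded).
#' @param n_neighbors Neighbours in the fuzzy graph.
#' @param min_dist Minimum embedding distance (controls the layout curve;
#'   only the default 0.1 curve constants are tabulated).
#' @param n_epochs Layout epochs.
#' @param n_neg Repulsion budget, as negative samples per edge per epoch.
#' @param learning_rate Initial step size.
#' @param seed Integer seed (kept for interface stability; the layout is
#'   fully deterministic).
#' @return n x 2 matrix of embedding coordinates.
#' @export
embed2d <- function(X, n_neighbors = 15, min_dist = 0.1, n_epochs = 300,
                    n_neg = 5, learning_rate = 1, seed = 1) {
  X0 <- as.matrix(X)
  n0 <- nrow(X0)
  stopifnot(n0 >= 2)
  # collapse exact duplicate rows: duplicates are one entity for the
  # layout (this keeps the embedding equivariant under row permutation
  # even with ties) and are re-expanded afterwards
  key <- apply(X0, 1, paste, collapse = "\r")
  rep_row <- match(key, key)
  uniq <- which(rep_row == seq_len(n0))
  X <- X0[uniq, , drop = FALSE]
  n <- nrow(X)
  if (n <= 4) {
    # too few distinct profiles for a graph layout: metric scaling
    Yu <- stats::cmdscale(dist(X), k = min(2, n - 1))
    if (ncol(Yu) < 2) Yu <- cbind(Yu, 0)
    Yu <- Yu / max(abs(Yu), 1e-12) * 10
    return(unname(Yu[match(rep_row, uniq), , drop = FALSE]))
  }
  k <- min(n_neighbors, n - 1)
  d2 <- outer(rowSums(X^2), rowSums(X^2), `+`) - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  diag(d2) <- Inf
  dmat <- sqrt(d2)
  knn <- t(apply(dmat, 1, function(r) order(r)[1:k]))
  kd <- t(vapply(seq_len(n), function(i) dmat[i, knn[i, ]], numeric(k)))
  rho <- kd[, 1]
  target <- log2(k)
  sigma <- vapply(seq_len(n), function(i) {
    di <- pmax(kd[i, ] - rho[i], 0)
    if (all(di == 0)) return(1)
    lo <- 1e-8; hi <- max(di) * 10
    for (it in 1:50) {
      mid <- (lo + hi) / 2
      s <- sum(exp(-di / mid))
      if (s > target) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  # directed membership strengths, then fuzzy union symmetrization
  w_dir <- exp(-pmax(kd - rho, 0) / sigma)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, knn[i, ]] <- w_dir[i, ]
  Ws <- W + t(W) - W * t(W)
  eidx <- which(Ws > 1e-8 & upper.tri(Ws), arr.ind = TRUE)
  ei <- eidx[, 1]; ej <- eidx[, 2]
  ew <- Ws[eidx]
  # layout curve constants for min_dist = 0.1, spread = 1
  a <- 1.577; b <- 0.8951
  pc <- prcomp(X, rank. = 2)
  Y <- pc$x[, 1:2, drop = FALSE]
  if (ncol(Y) < 2) Y <- cbind(Y, 0)
  # deterministic sign: largest-magnitude coordinate positive
  for (j in 1:2) {
    m <- which.max(abs(Y[, j]))
    if (Y[m, j] < 0) Y[, j] <- -Y[, j]
  }
  sc <- max(abs(Y), 1e-12)
  Y <- Y / sc * 10
  # data-derived jitter to split exact duplicates without breaking
  # permutation equivariance
  h <- rowSums(X) + 0.7 * rowSums(X^2)
  Y <- Y + 1e-4 * cbind(sin(1e3 * h), cos(1e3 * h))
  m_edges <- length(ei)
  # all-pairs repulsion scaled to the negative-sampling budget
  gamma <- (n_neg * 2 * m_edges) / (n * (n - 1))
  for (ep in seq_len(n_epochs)) {
    alpha <- learning_rate * (1 - (ep - 1) / n_epochs)
    diffv <- Y[ei, , drop = FALSE] - Y[ej, , drop = FALSE]
    dd2 <- rowSums(diffv^2)
    coef <- (-2 * a * b * dd2^(b - 1)) / (1 + a * dd2^b)
    coef[dd2 == 0] <- 0
    gmove <- pmin(pmax(coef * ew, -4), 4) * diffv
    upd <- rowsum(rbind(gmove, -gmove), c(ei, ej))
    rows <- as.integer(rownames(upd))
    Y[rows, ] <- Y[rows, ] + alpha * upd
    # deterministic repulsion over all pairs
    D2 <- outer(rowSums(Y^2), rowSums(Y^2), `+`) - 2 * tcrossprod(Y)
    D2[D2 < 0] <- 0
    Rw <- (2 * b) / ((0.001 + D2) * (1 + a * D2^b)) * gamma
    Rw[Rw > 4] <- 4
    diag(Rw) <- 0
    push <- rowSums(Rw) * Y - Rw %*% Y
    Y <- Y + alpha * push
  }
  unname(Y[match(rep_row, uniq), , drop = FALSE])
}

#' Density-based clustering (DBSCAN)
#'
#' Classic DBSCAN on Euclidean distances. When `eps` is not given it is
#' chosen from the sorted 4-NN distance curve at its knee (largest
#' distance to the chord between the curve's endpoints), falling back to
#' the 0.9 quantile when the knee is degenerate.
#'
#' @param X n x d matrix.
#' @param eps Neighbourhood radius; `NULL` to auto-select.
#' @param min_pts Minimum neighbourhood size of a core point.
#' @return Integer labels: clusters numbered from 1, noise = -1;
#'   attribute `eps` records the radius used.
#' @export
dbscan_cluster <- function(X, eps = NULL, min_pts = 5) {
  X <- as.matrix(X)
  n <- nrow(X)
  d2 <- outer(rowSums(X^2), rowSums(X^2), `+`) - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  dmat <- sqrt(d2)
  if (is.null(eps)) {
    k4 <- apply(dmat, 1, function(r) sort(r)[min(5, n)])  # 4-NN (+self)
    s <- sort(k4)
    m <- length(s)
    # knee of the 4-NN curve, read from the top: a large relative jump in
    # the top quarter separates isolated points (noise) from the
    # within-cluster distance scale. With no jump every point is treated
    # as core (dense, well-separated clusters). Duplicated or collapsed
    # points only flatten the bottom of the curve and cannot drag eps
    # down.
    eps <- NA_real_
    idx <- seq(max(1, ceiling(0.75 * m)), m - 1)
    if (length(idx) > 0 && s[m] > 0) {
      ratio <- s[idx + 1] / pmax(s[idx], 1e-12)
      if (max(ratio) > 2) {
        j <- idx[which.max(ratio)]
        eps <- s[j] * 1.25
      }
    }
    if (!is.finite(eps) || eps <= 0) {
      eps <- 1.05 * max(s)             # quantile-top fallback: all core
    }
    if (!is.finite(eps) || eps <= 0) eps <- 1e-12
  }
  nb <- lapply(seq_len(n), function(i) which(dmat[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != -1L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      if (labels[j] == -1L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == -1L])
      }
    }
  }
  attr(labels, "eps") <- eps
  labels
}
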