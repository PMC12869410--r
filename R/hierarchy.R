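#' Precomputed point hierarchy for the PT decoder
#'
#' The decoder works on a fixed multi-level point hierarchy derived once
#' from the neutral GMM: level point sets of increasing size (k-means
#' centroids of the neutral centres; the last level is the centres
#' themselves), per-level k-nearest-neighbour tables for self-attention,
#' inverse-distance interpolation tables between consecutive levels for
#' transition-up, and direct interpolation tables from the intermediate
#' levels to the full GMM for the residual branches. Because the decoder
#' outputs only changes relative to the neutral model, the geometry is
#' shared by all particles and is precomputed once.
#'
#' @param neutral_centers N x 3 matrix of neutral GMM centres (box units).
#' @param level_sizes Strictly ascending level sizes; the last must equal
#'   N. Default `c(64, 256, N)`.
#' @param k_attn Neighbours per point for self-attention (must be smaller
#'   than the smallest level).
#' @param seed Integer seed for the k-means restarts.
#' @return A `pt_hierarchy` object with fields `level_points`,
#'   `neighbor_idx`, `up_idx`, `up_weight`, `resid_up`.
#' @export
build_hierarchy <- function(neutral_centers, level_sizes = NULL,
                            k_attn = 16, seed = 1) {
  neutral_centers <- as.matrix(neutral_centers)
  N <- nrow(neutral_centers)
  if (is.null(level_sizes)) level_sizes <- c(64, 256, N)
  L <- length(level_sizes)
  if (any(diff(level_sizes) <= 0) && L > 1) {
    stop("level_sizes must be strictly ascending")
  }
  if (level_sizes[L] != N) stop("last level size must equal the GMM size")
  if (any(level_sizes > N)) stop("level size exceeds the GMM size")
  if (k_attn >= min(level_sizes)) {
    stop("k_attn must be smaller than the smallest level")
  }
  set.seed(seed)
  level_points <- vector("list", L)
  for (l in seq_len(L)) {
    P <- level_sizes[l]
    if (P == N) {
      level_points[[l]] <- neutral_centers
    } else {
      km <- kmeans(neutral_centers, centers = P, nstart = 10,
                   iter.max = 100)
      level_points[[l]] <- unname(km$centers)
    }
  }
  neighbor_idx <- lapply(level_points, function(pts) {
    knn_index(pts, pts, k_attn, self = TRUE)
  })
  up <- vector("list", max(L - 1, 0))
  if (L > 1) {
    for (l in seq_len(L - 1)) {
      up[[l]] <- interp_table(level_points[[l + 1]], level_points[[l]])
    }
  }
  resid_up <- NULL
  if (L > 2) {
    resid_up <- lapply(seq_len(L - 1), function(l) {
      interp_table(neutral_centers, level_points[[l]])
    })
  }
  structure(list(level_points = level_points,
                 level_sizes = level_sizes,
                 neighbor_idx = neighbor_idx,
                 up = up,
                 resid_up = resid_up,
                 k_attn = k_attn,
                 seed = seed),
            class = "pt_hierarchy")
}

#' @export
print.pt_hierarchy <- function(x, ...) {
  cat(sprintf("<pt_hierarchy> levels [%s], k_attn %d\n",
              paste(x$level_sizes, collapse = ", "), x$k_attn))
  invisible(x)
}

# k nearest neighbours of each query row among pts rows. With self = TRUE
# (and query identical to pts) the point itself is included as its first
# neighbour, as in the PT self-attention neighbourhood.
knn_index <- function(query, pts, k, self = TRUE) {
  d2 <- outer(rowSums(query^2), rowSums(pts^2), `+`) - 2 * query %*% t(pts)
  t(apply(d2, 1, function(row) order(row)[1:k]))
}

# Inverse-distance interpolation: 3 nearest coarse points per fine point.
interp_table <- function(fine, coarse, n_interp = 3) {
  n_interp <- min(n_interp, nrow(coarse))
  d2 <- outer(rowSums(fine^2), rowSums(coarse^2), `+`) -
    2 * fine %*% t(coarse)
  d2[d2 < 0] <- 0
  idx <- t(apply(d2, 1, function(row) order(row)[1:n_interp]))
  d <- sqrt(t(vapply(seq_len(nrow(fine)),
                     function(i) d2[i, idx[i, ]], numeric(n_interp))))
  w <- 1 / pmax(d, 1e-12)
  # exact coincidence: all weight on the coincident coarse point
  hit <- d[, 1] < 1e-12
  if (any(hit)) {
    w[hit, ] <- 0
    w[hit, 1] <- 1
  }
  w <- w / rowSums(w)
  list(idx = idx, weight = w)
}
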