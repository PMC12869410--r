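#' Gaussian mixture density model
#'
#' Protein density represented as `N` isotropic 3-D Gaussians: centres in
#' box-normalized units (fractions of the box edge, nominally in
#' `[-0.5, 0.5]`, with slack to `[-0.6, 0.6]` so decoded motion may move
#' centres slightly outside the nominal box), non-negative amplitudes and
#' strictly positive widths (standard deviation, box units).
#'
#' @param centers N x 3 numeric matrix.
#' @param amplitudes Length-N non-negative numeric.
#' @param widths Length-N positive numeric.
#' @return A `gmm` object.
#' @export
gmm <- function(centers, amplitudes, widths) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 3, nrow(centers) >= 1)
  N <- nrow(centers)
  if (length(widths) == 1) widths <- rep(widths, N)
  if (length(amplitudes) == 1) amplitudes <- rep(amplitudes, N)
  obj <- structure(list(centers = centers,
                        amplitudes = as.numeric(amplitudes),
                        widths = as.numeric(widths)),
                   class = "gmm")
  validate_gmm(obj)
}

validate_gmm <- function(g) {
  if (!all(is.finite(g$centers)) || !all(is.finite(g$amplitudes)) ||
      !all(is.finite(g$widths))) {
    stop("gmm contains non-finite values")
  }
  if (length(g$amplitudes) != nrow(g$centers) ||
      length(g$widths) != nrow(g$centers)) {
    stop("gmm field lengths disagree")
  }
  if (any(g$amplitudes < 0)) stop("gmm amplitudes must be >= 0")
  if (any(g$widths <= 0)) stop("gmm widths must be > 0")
  if (any(abs(g$centers) > 0.6)) {
    stop("gmm centers outside [-0.6, 0.6] box-normalized range")
  }
  g
}

#' @export
print.gmm <- function(x, ...) {
  cat(sprintf("<gmm> %d Gaussians, mean amplitude %.3f, width range [%.4f, %.4f]\n",
              nrow(x$centers), mean(x$amplitudes), min(x$widths),
              max(x$widths)))
  invisible(x)
}

#' @export
tidy.gmm <- function(x, ...) {
  tibble::tibble(gaussian = seq_len(nrow(x$centers)),
                 x = x$centers[, 1], y = x$centers[, 2], z = x$centers[, 3],
                 amplitude = x$amplitudes, width = x$widths)
}

#' Seed a neutral GMM from a structure by k-means
#'
#' Cluster the structure's points (in box units) into `n_gaussians`
#' k-means centroids; each Gaussian's amplitude is proportional to the
#' total point weight of its cluster, normalized so the mean amplitude is
#' exactly 1, and all widths start at `width0`.
#'
#' @param structure A [protein_structure()].
#' @param n_gaussians Number of Gaussians (<= number of points).
#' @param width0 Initial width (box units).
#' @param seed Integer seed (k-means restarts are deterministic given it).
#' @return A [gmm()].
#' @export
seed_gmm_from_structure <- function(structure, n_gaussians, width0 = 0.02,
                                    seed = 1) {
  stopifnot(n_gaussians >= 1)
  coords <- structure_coords_box(structure)
  if (n_gaussians > nrow(coords)) {
    stop("n_gaussians exceeds the number of structure points")
  }
  if (n_gaussians == nrow(coords)) {
    centers <- coords
    cl <- seq_len(nrow(coords))
  } else if (n_gaussians == 1) {
    centers <- matrix(colMeans(coords), 1, 3)
    cl <- rep(1L, nrow(coords))
  } else {
    set.seed(seed)
    km <- kmeans(coords, centers = n_gaussians, nstart = 10,
                 iter.max = 100)
    centers <- km$centers
    cl <- km$cluster
  }
  mass <- as.numeric(rowsum(structure$weight, cl))
  amps <- mass / mean(mass)
  gmm(centers, amps, rep(width0, n_gaussians))
}

#' Render a GMM on a cubic voxel grid
#'
#' Voxel `(i, j, l)` (0-based) sits at box coordinate `(i - g/2) / g` and
#' holds `sum_i amp_i exp(-|r - c_i|^2 / (2 sigma_i^2))`, so a unit
#' Gaussian peaks at 1 and integrates (in grid units) to
#' `amp * (2 pi sigma_g^2)^{3/2}` with `sigma_g` in voxels.
#'
#' @param gmm A [gmm()].
#' @param grid_size Cubic grid edge in voxels (>= 8).
#' @return A `grid_size^3` numeric array.
#' @export
render_volume <- function(gmm, grid_size = 64) {
  stopifnot(grid_size >= 8)
  ax <- (seq_len(grid_size) - 1 - grid_size / 2) / grid_size
  vol <- array(0, dim = rep(grid_size, 3))
  for (i in seq_len(nrow(gmm$centers))) {
    s2 <- 2 * gmm$widths[i]^2
    gx <- exp(-(ax - gmm$centers[i, 1])^2 / s2)
    gy <- exp(-(ax - gmm$centers[i, 2])^2 / s2)
    gz <- exp(-(ax - gmm$centers[i, 3])^2 / s2)
    vol <- vol + gmm$amplitudes[i] * outer(outer(gx, gy), gz)
  }
  vol
}

#' Match Gaussians to their nearest structure points
#'
#' Assigns every Gaussian the segment label of its nearest structure point
#' (Euclidean distance in box-normalized coordinates); ties break to the
#' lowest point index. Rejects structures whose points fall outside the
#' box (frame mismatch).
#'
#' @param gmm A [gmm()].
#' @param structure A [protein_structure()] in the same frame.
#' @return Tibble with columns `gaussian`, `atom`, `segment`.
#' @export
map_gaussians_to_atoms <- function(gmm, structure) {
  atoms <- structure_coords_box(structure)
  if (any(abs(atoms) > 0.5 + 1e-9)) {
    stop("structure coordinates fall outside the box: frame mismatch")
  }
  nearest <- nearest_index(gmm$centers, atoms)
  tibble::tibble(gaussian = seq_len(nrow(gmm$centers)),
                 atom = nearest,
                 segment = structure$segment[nearest])
}

# Index of the nearest row of `pts` for each row of `query`; ties go to
# the lowest index (which.max on strict improvement).
nearest_index <- function(query, pts, chunk = 512L) {
  n <- nrow(query)
  out <- integer(n)
  p2 <- rowSums(pts^2)
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), p2, `+`) - 2 * q %*% t(pts)
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}
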