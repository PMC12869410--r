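#' Per-Gaussian output profiles across particles
#'
#' Builds the matrix embedded by [segment_gmm()]: one row per Gaussian,
#' one column per sampled particle, holding the decoded amplitude gate
#' (channel `"amplitude"`) or the centre-shift magnitude in box units
#' (channel `"motion"`). Particles are a seeded uniform subsample of at
#' most `max_particles` (column order follows particle order). Rows are
#' z-scored by default so clustering reflects the pattern, not the
#' scale, of each Gaussian's changes.
#'
#' @param outputs A `ptgmm_particles`.
#' @param channel `"amplitude"` or `"motion"`.
#' @param max_particles Subsample size cap.
#' @param standardize Z-score rows.
#' @param seed Integer seed for the subsample.
#' @return A `gaussian_features` matrix (N x n_sample) with attribute
#'   `particles` (the sampled indices).
#' @export
build_feature_matrix <- function(outputs, channel = c("amplitude", "motion"),
                                 max_particles = 2000, standardize = TRUE,
                                 seed = 1) {
  channel <- match.arg(channel)
  n <- nrow(outputs$gate)
  if (n < 1) stop("empty outputs table")
  if (channel == "motion" && all(outputs$d_center == 0) &&
      outputs$decoder_type == "oracle") {
    stop("motion channel absent from these outputs")
  }
  if (n > max_particles) {
    set.seed(seed)
    keep <- sort(sample.int(n, max_particles))
  } else {
    keep <- seq_len(n)
  }
  feat <- switch(channel,
    amplitude = t(outputs$gate[keep, , drop = FALSE]),
    motion = t(sqrt(outputs$d_center[keep, , 1]^2 +
                    outputs$d_center[keep, , 2]^2 +
                    outputs$d_center[keep, , 3]^2)))
  if (standardize) {
    mu <- rowMeans(feat)
    sdv <- apply(feat, 1, sd)
    feat <- (feat - mu) / ifelse(sdv > 0, sdv, 1)
  }
  attr(feat, "particles") <- keep
  attr(feat, "channel") <- channel
  class(feat) <- c("gaussian_features", class(feat))
  feat
}

#' Segment the GMM into regions of correlated dynamics
#'
#' Embeds the per-Gaussian output profiles to 2-D ([embed2d()]) and
#' density-clusters the embedding ([dbscan_cluster()]). Clusters are
#' groups of Gaussians whose decoder outputs co-vary across particles —
#' parts that assemble or move as one unit. If everything is labelled
#' noise the whole GMM is returned as a single region with a warning.
#'
#' @param features A [build_feature_matrix()] result.
#' @param n_neighbors,min_dist,n_epochs Embedding parameters.
#' @param eps,min_pts DBSCAN parameters (`eps = NULL` auto-selects).
#' @param seed Integer seed.
#' @return A `region_set` tibble: `gaussian`, `region` (-1 = noise),
#'   `emb1`, `emb2`.
#' @export
segment_gmm <- function(features, n_neighbors = 15, min_dist = 0.1,
                        n_epochs = 300, eps = NULL, min_pts = 5,
                        seed = 1) {
  stopifnot(nrow(features) >= 10)
  emb <- embed2d(unclass(features), n_neighbors = n_neighbors,
                 min_dist = min_dist, n_epochs = n_epochs, seed = seed)
  labels <- dbscan_cluster(emb, eps = eps, min_pts = min_pts)
  if (all(labels == -1L)) {
    warning("all Gaussians labelled noise; returning a single region")
    labels[] <- 1L
  }
  out <- tibble::tibble(gaussian = seq_len(nrow(features)),
                        region = as.integer(labels),
                        emb1 = emb[, 1], emb2 = emb[, 2])
  class(out) <- c("region_set", class(out))
  attr(out, "eps") <- attr(labels, "eps")
  out
}

#' Match recovered regions to true segments
#'
#' A toggleable segment counts as correctly separated when some region's
#' Gaussians are majority-drawn from it and the segment's Gaussians are
#' majority-assigned to that region (a mutual majority match).
#'
#' @param regions A `region_set`.
#' @param gmm_map From [map_gaussians_to_atoms()].
#' @param exclude_core Ignore segment 0 when counting.
#' @return List with `n_matched`, and a `table` tibble of region/segment
#'   majorities.
#' @export
match_regions_to_segments <- function(regions, gmm_map,
                                      exclude_core = TRUE) {
  seg <- gmm_map$segment
  lab <- regions$region
  segs <- sort(unique(seg))
  if (exclude_core) segs <- setdiff(segs, 0L)
  rows <- list()
  n_matched <- 0L
  for (s in segs) {
    in_seg <- seg == s
    reg_counts <- table(lab[in_seg])
    top_reg <- as.integer(names(reg_counts)[which.max(reg_counts)])
    seg_maj <- max(reg_counts) / sum(in_seg)
    in_reg <- lab == top_reg & top_reg != -1L
    reg_maj <- if (any(in_reg)) mean(seg[in_reg] == s) else 0
    ok <- top_reg != -1L && seg_maj > 0.5 && reg_maj > 0.5
    if (ok) n_matched <- n_matched + 1L
    rows[[length(rows) + 1]] <- tibble::tibble(
      segment = s, region = top_reg, segment_majority = seg_maj,
      region_majority = reg_maj, matched = ok)
  }
  list(n_matched = n_matched, table = dplyr::bind_rows(rows))
}

#' Region-focused particle embedding and classification
#'
#' Embeds all particles to 2-D using only the decoder outputs of one
#' region's Gaussians, then k-means-classifies the embedding. This
#' isolates the structural heterogeneity of the chosen region from
#' everything else the molecule is doing.
#'
#' @param outputs A `ptgmm_particles`.
#' @param regions A `region_set`.
#' @param region Region label to focus on.
#' @param k Number of k-means classes.
#' @param channel `"amplitude"` or `"motion"` feature channel.
#' @param n_neighbors,n_epochs Embedding parameters.
#' @param min_size Minimum Gaussians required in the region.
#' @param seed Integer seed.
#' @return A `particle_embedding` tibble: `particle`, `emb1`, `emb2`,
#'   `class`.
#' @export
focus_embed_particles <- function(outputs, regions, region, k = 2,
                                  channel = c("amplitude", "motion"),
                                  n_neighbors = 15, n_epochs = 300,
                                  min_size = 3, seed = 1) {
  channel <- match.arg(channel)
  gsel <- regions$gaussian[regions$region == region]
  if (length(gsel) == 0) stop("empty region")
  if (length(gsel) < min_size) {
    stop(sprintf("region %d has %d Gaussians; need >= %d", region,
                 length(gsel), min_size))
  }
  feat <- switch(channel,
    amplitude = outputs$gate[, gsel, drop = FALSE],
    motion = {
      dc <- outputs$d_center[, gsel, , drop = FALSE]
      cbind(dc[, , 1], dc[, , 2], dc[, , 3])
    })
  emb <- embed2d(feat, n_neighbors = n_neighbors, n_epochs = n_epochs,
                 seed = seed)
  set.seed(seed + 1)
  cls <- if (k == 1) rep(1L, nrow(emb)) else {
    kmeans(emb, centers = k, nstart = 10)$cluster
  }
  out <- tibble::tibble(particle = seq_len(nrow(emb)),
                        emb1 = emb[, 1], emb2 = emb[, 2],
                        class = as.integer(cls))
  class(out) <- c("particle_embedding", class(out))
  attr(out, "region") <- region
  out
}

#' Difference volume between two particle classes
#'
#' Averages the decoder outputs within each class, applies them to the
#' neutral GMM, renders both volumes and returns their difference
#' (class A minus class B), the per-class mean GMMs, and the class
#' means.
#'
#' @param outputs A `ptgmm_particles`.
#' @param classes Integer class label per particle (e.g. the `class`
#'   column of [focus_embed_particles()]).
#' @param neutral The neutral [gmm()].
#' @param grid_size Rendering grid edge.
#' @param class_a,class_b The two classes to contrast.
#' @return List with `volume` (3-D array, A - B), `gmm_a`, `gmm_b`.
#' @export
class_difference_volume <- function(outputs, classes, neutral,
                                    grid_size = 64, class_a = 1,
                                    class_b = 2) {
  if (inherits(classes, "data.frame")) classes <- classes$class
  stopifnot(length(classes) == nrow(outputs$gate))
  mean_out <- function(cl) {
    sel <- which(classes == cl)
    if (!length(sel)) stop(sprintf("class %s has no particles", cl))
    list(d_center = apply(outputs$d_center[sel, , , drop = FALSE],
                          c(2, 3), mean),
         d_amplitude = colMeans(outputs$d_amplitude[sel, , drop = FALSE]),
         d_sigma = colMeans(outputs$d_sigma[sel, , drop = FALSE]))
  }
  ga <- apply_deltas(neutral, mean_out(class_a))
  gb <- apply_deltas(neutral, mean_out(class_b))
  list(volume = render_volume(ga, grid_size) - render_volume(gb, grid_size),
       gmm_a = ga, gmm_b = gb)
}
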