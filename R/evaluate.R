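#' Oracle decoder outputs from compositional ground truth
#'
#' Builds the decoder-output table a perfect model would produce: every
#' Gaussian's amplitude gate equals the true presence (1/0) of its
#' segment in each particle, with zero centre and width changes. Used to
#' validate the evaluation and interpretability stages independently of
#' training.
#'
#' @param sim A `comp_simulation`.
#' @param gmm_map Gaussian-to-atom map from [map_gaussians_to_atoms()].
#' @param neutral The neutral [gmm()].
#' @return A `ptgmm_particles` object.
#' @export
oracle_outputs <- function(sim, gmm_map, neutral) {
  n <- sim$n_particles
  N <- nrow(gmm_map)
  pres <- sim$presence[, gmm_map$segment + 1L, drop = FALSE]  # n x N
  da <- pres - 1                       # gate(0) = 1 present, gate(-1) = 0
  structure(list(latent = matrix(0, n, 0),
                 d_center = array(0, c(n, N, 3)),
                 d_amplitude = da,
                 d_sigma = matrix(0, n, N),
                 gate = amplitude_gate(da),
                 neutral = neutral,
                 box_size_A = NA_real_,
                 decoder_type = "oracle"),
            class = "ptgmm_particles")
}

#' Amplitude classification accuracy against compositional ground truth
#'
#' Each (particle, Gaussian) pair is predicted "present" when the
#' decoded amplitude gate is at least `threshold`; the prediction is
#' compared with the true presence of the Gaussian's segment in that
#' particle. Accuracy is pooled over all predictions for Gaussians of
#' toggleable segments (the core segment's truth is constant and is
#' excluded by default).
#'
#' @param outputs A `ptgmm_particles` (from [infer()] or
#'   [oracle_outputs()]).
#' @param gmm_map From [map_gaussians_to_atoms()]; must cover every
#'   Gaussian.
#' @param truth A `comp_simulation` (or its presence matrix).
#' @param threshold Gate cutoff for "present" (default 0.5).
#' @param include_core Also count core-segment Gaussians.
#' @return An `amplitude_accuracy` list: `accuracy`, `per_segment`
#'   tibble, and the `histogram` tibble of gate values split by true
#'   presence.
#' @export
amplitude_accuracy <- function(outputs, gmm_map, truth, threshold = 0.5,
                               include_core = FALSE) {
  pres <- if (inherits(truth, "comp_simulation")) truth$presence else truth
  N <- ncol(outputs$gate)
  if (nrow(gmm_map) != N || anyNA(gmm_map$segment)) {
    stop("every Gaussian must be mapped to a segment")
  }
  stopifnot(threshold > 0, nrow(pres) == nrow(outputs$gate))
  seg <- gmm_map$segment
  keep <- if (include_core) rep(TRUE, N) else seg != 0L
  gate <- outputs$gate[, keep, drop = FALSE]
  tru <- pres[, seg[keep] + 1L, drop = FALSE]
  pred <- gate >= threshold
  acc <- mean(pred == tru)
  per_seg <- tibble::tibble(segment = seg[keep],
                            correct = colMeans(pred == tru)) |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(accuracy = mean(.data$correct),
                     n_gaussians = dplyr::n(), .groups = "drop")
  hist_tbl <- tibble::tibble(amplitude = as.vector(gate),
                             true_present = as.vector(tru))
  structure(list(accuracy = acc, per_segment = per_seg,
                 histogram = hist_tbl, threshold = threshold),
            class = "amplitude_accuracy")
}

#' @export
print.amplitude_accuracy <- function(x, ...) {
  cat(sprintf("<amplitude_accuracy> %.1f%% at threshold %.2f over %d segments\n",
              100 * x$accuracy, x$threshold, nrow(x$per_segment)))
  invisible(x)
}

#' @export
glance.amplitude_accuracy <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, threshold = x$threshold,
                 n_segments = nrow(x$per_segment))
}

#' Per-particle motion RMSD against conformational ground truth
#'
#' Every atom's predicted displacement is its nearest Gaussian's decoded
#' centre shift (converted from box units to Angstrom); the per-particle
#' RMSD over all atoms is compared with the ground-truth displacement.
#' The no-motion baseline (zero prediction) equals the ground-truth
#' movement magnitude and is reported alongside.
#'
#' @param outputs A `ptgmm_particles`.
#' @param neutral The neutral [gmm()].
#' @param gmm_map From [map_gaussians_to_atoms()] (fixes the coordinate
#'   frame/box).
#' @param truth A `motion_simulation`.
#' @param k_transfer Gaussians per atom for the displacement transfer:
#'   1 (default) uses the single nearest Gaussian; larger values average
#'   the k nearest with inverse-distance weights.
#' @return A tibble with columns `particle`, `rmsd`, `baseline`
#'   (Angstrom), with the means as attributes `mean_rmsd`,
#'   `mean_baseline`.
#' @export
motion_rmsd <- function(outputs, neutral, gmm_map, truth, k_transfer = 1) {
  box_A <- box_size(truth$structure)
  if (is.finite(outputs$box_size_A) &&
      abs(outputs$box_size_A - box_A) > 1e-6 * box_A) {
    stop("box size mismatch between outputs and ground truth (units)")
  }
  atoms_box <- structure_coords_box(truth$structure)
  if (k_transfer == 1) {
    near_g <- nearest_index(atoms_box, neutral$centers)
    transfer <- function(dc) dc[near_g, , drop = FALSE]
  } else {
    tab <- interp_table(atoms_box, neutral$centers,
                        n_interp = k_transfer)
    transfer <- function(dc) {
      out <- tab$weight[, 1] * dc[tab$idx[, 1], , drop = FALSE]
      for (t in 2:ncol(tab$idx)) {
        out <- out + tab$weight[, t] * dc[tab$idx[, t], , drop = FALSE]
      }
      out
    }
  }
  n <- truth$n_particles
  rmsd <- numeric(n)
  base <- numeric(n)
  for (i in seq_len(n)) {
    tr <- motion_displacement(truth, i)
    pred <- transfer(outputs$d_center[i, , ]) * box_A
    rmsd[i] <- sqrt(mean(rowSums((pred - tr)^2)))
    base[i] <- sqrt(mean(rowSums(tr^2)))
  }
  out <- tibble::tibble(particle = seq_len(n), rmsd = rmsd,
                        baseline = base)
  attr(out, "mean_rmsd") <- mean(rmsd)
  attr(out, "mean_baseline") <- mean(base)
  out
}
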