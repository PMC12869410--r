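#' Toy segmented structure
#'
#' Generates a download-free stand-in for a segmented macromolecule: a
#' large central core blob (segment 0) surrounded by `n_segments - 1`
#' compact peripheral blobs placed on a spherical shell (Fibonacci
#' layout), each a uniform-ball point cloud. Peripheral blob radii vary
#' by +/-20% so the segments have variable sizes. Blobs must clear each
#' other by at least one blob radius (centroid separation >= 3 radii);
#' an infeasible layout is rejected with advice.
#'
#' @param n_segments Total segment count including the core (>= 2).
#' @param pts_per_segment Points per peripheral segment; the core gets
#'   2.5x as many.
#' @param seed Integer seed.
#' @param box_size_A Box edge (Angstrom).
#' @param core_radius_A,blob_radius_A,shell_radius_A Layout radii.
#' @return A [protein_structure()].
#' @export
make_toy_structure <- function(n_segments = 9, pts_per_segment = 90,
                               seed = 1, box_size_A = 160,
                               core_radius_A = 18, blob_radius_A = 9,
                               shell_radius_A = 34) {
  stopifnot(n_segments >= 2)
  set.seed(seed)
  nb <- n_segments - 1
  # Fibonacci sphere directions for the peripheral centroids
  i <- seq_len(nb) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  cz <- 1 - 2 * i / nb
  cr <- sqrt(pmax(0, 1 - cz^2))
  cen <- cbind(cr * cos(phi), cr * sin(phi), cz) * shell_radius_A
  if (nb > 1) {
    dmin <- min(dist(cen))
    if (dmin < 3 * blob_radius_A) {
      stop(sprintf(paste0(
        "infeasible packing: min centroid distance %.1f A < %.1f A; ",
        "increase shell_radius_A or reduce blob_radius_A"),
        dmin, 3 * blob_radius_A))
    }
  }
  ball <- function(n, radius, centre) {
    u <- matrix(rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    r <- radius * runif(n)^(1 / 3)
    sweep(u * r, 2, centre, `+`)
  }
  n_core <- round(2.5 * pts_per_segment)
  coords <- ball(n_core, core_radius_A, c(0, 0, 0))
  segs <- rep(0L, n_core)
  radii <- blob_radius_A * runif(nb, 0.8, 1.2)
  for (s in seq_len(nb)) {
    coords <- rbind(coords, ball(pts_per_segment, radii[s], cen[s, ]))
    segs <- c(segs, rep(s, pts_per_segment))
  }
  protein_structure(coords, segs, box_size_A = box_size_A)
}

#' Simulate compositional heterogeneity
#'
#' Every non-core segment is independently absent with probability
#' `p_absent` in each particle; segment 0 (the core) is always present.
#' With 8 toggleable segments at `p_absent = 0.5` the design yields 256
#' equally likely compositional states.
#'
#' @param structure A segmented [protein_structure()].
#' @param n_particles Number of particles.
#' @param p_absent Per-segment absence probability.
#' @param seed Integer seed.
#' @return A `comp_simulation`: the structure, an `n x K` logical
#'   `presence` matrix and integer `state_id` per particle (binary
#'   encoding of the toggleable segments).
#' @export
simulate_compositional <- function(structure, n_particles, p_absent = 0.5,
                                   seed = 1) {
  K <- max(structure$segment) + 1L
  stopifnot(K >= 2)
  set.seed(seed)
  presence <- matrix(TRUE, n_particles, K)
  if (K > 1) {
    presence[, -1] <- matrix(runif(n_particles * (K - 1)) >= p_absent,
                             n_particles, K - 1)
  }
  state_id <- as.integer(presence[, -1, drop = FALSE] %*% 2^(0:(K - 2)))
  structure(list(structure = structure, presence = presence,
                 state_id = state_id, n_particles = n_particles,
                 p_absent = p_absent, seed = seed),
            class = "comp_simulation")
}

#' @export
print.comp_simulation <- function(x, ...) {
  cat(sprintf("<comp_simulation> %d particles, %d segments, %d distinct states\n",
              x$n_particles, ncol(x$presence),
              length(unique(x$state_id))))
  invisible(x)
}

#' @export
tidy.comp_simulation <- function(x, ...) {
  pres <- tibble::as_tibble(x$presence, .name_repair = "minimal")
  names(pres) <- paste0("seg_", seq_len(ncol(x$presence)) - 1)
  dplyr::bind_cols(tibble::tibble(particle = seq_len(x$n_particles),
                                  state_id = x$state_id), pres)
}

# Coordinates (Angstrom) of one particle of a simulation.
particle_coords <- function(sim, i, ...) UseMethod("particle_coords")

#' @export
particle_coords.comp_simulation <- function(sim, i, ...) {
  keep <- sim$presence[i, sim$structure$segment + 1L]
  list(coords = structure_coords(sim$structure)[keep, , drop = FALSE],
       weights = sim$structure$weight[keep])
}

#' Simulate continuous rigid-domain motion
#'
#' Selected regions (segment id sets) are rigidly rotated about fixed
#' axes by independent per-particle angles drawn uniformly from
#' `[-angle_range/2, +angle_range/2]` degrees; every particle is built
#' from one such model, giving true continuous heterogeneity. The axis of
#' each region passes through `axes[[r]]$point` (Angstrom) along the unit
#' vector `axes[[r]]$direction`.
#'
#' @param structure A segmented [protein_structure()].
#' @param regions List (length R) of integer vectors of segment ids; the
#'   regions must be disjoint.
#' @param axes List (length R) of `list(point, direction)`.
#' @param angle_range Full width of the uniform angle distribution
#'   (degrees).
#' @param n_particles Number of particles.
#' @param seed Integer seed.
#' @return A `motion_simulation` with the per-particle `angles` matrix
#'   (degrees).
#' @export
simulate_motion <- function(structure, regions, axes, angle_range,
                            n_particles, seed = 1) {
  R <- length(regions)
  stopifnot(R >= 1, length(axes) == R)
  if (anyDuplicated(unlist(regions))) stop("regions must be disjoint")
  axes <- lapply(axes, function(a) {
    a$direction <- a$direction / sqrt(sum(a$direction^2))
    a
  })
  set.seed(seed)
  angles <- matrix(runif(n_particles * R, -angle_range / 2,
                         angle_range / 2), n_particles, R)
  structure(list(structure = structure, regions = regions, axes = axes,
                 angle_range = angle_range, angles = angles,
                 n_particles = n_particles, seed = seed),
            class = "motion_simulation")
}

#' @export
print.motion_simulation <- function(x, ...) {
  cat(sprintf("<motion_simulation> %d particles, %d moving regions, range %.1f deg\n",
              x$n_particles, length(x$regions), x$angle_range))
  invisible(x)
}

#' @export
tidy.motion_simulation <- function(x, ...) {
  ang <- tibble::as_tibble(x$angles, .name_repair = "minimal")
  names(ang) <- paste0("angle_", seq_along(x$regions))
  dplyr::bind_cols(tibble::tibble(particle = seq_len(x$n_particles)), ang)
}

axis_rotation <- function(direction, angle_rad) {
  u <- direction / sqrt(sum(direction^2))
  c0 <- cos(angle_rad); s0 <- sin(angle_rad)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  c0 * diag(3) + s0 * ux + (1 - c0) * (u %o% u)
}

#' @export
particle_coords.motion_simulation <- function(sim, i, ...) {
  co <- structure_coords(sim$structure)
  for (r in seq_along(sim$regions)) {
    sel <- sim$structure$segment %in% sim$regions[[r]]
    ax <- sim$axes[[r]]
    Rm <- axis_rotation(ax$direction, deg2rad(sim$angles[i, r]))
    co[sel, ] <- sweep(sweep(co[sel, , drop = FALSE], 2, ax$point) %*%
                         t(Rm), 2, ax$point, `+`)
  }
  list(coords = co, weights = sim$structure$weight)
}

#' Per-atom ground-truth displacement of one particle
#'
#' @param sim A `motion_simulation`.
#' @param i Particle index.
#' @return M x 3 matrix (Angstrom); zero outside the moving regions.
#' @export
motion_displacement <- function(sim, i) {
  particle_coords(sim, i)$coords - structure_coords(sim$structure)
}

#' Expected mean per-particle atomic RMSD of a motion simulation
#'
#' For a single region the closed form
#' `E[RMSD] = 2 sqrt(sum r_a^2 / M) * 4 (1 - cos(a/4)) / a`
#' (angles uniform on `[-a/2, a/2]`, `r_a` the atom-to-axis distances) is
#' used; with several regions the expectation is evaluated by a
#' deterministic low-discrepancy quadrature over the angle cube.
#'
#' @param structure,regions,axes,angle_range As in [simulate_motion()].
#' @param n_quad Quadrature points for the multi-region case.
#' @return Expected mean per-particle RMSD in Angstrom (over all atoms).
#' @export
expected_motion_rmsd <- function(structure, regions, axes, angle_range,
                                 n_quad = 20000) {
  co <- structure_coords(structure)
  M <- nrow(co)
  a <- deg2rad(angle_range)
  if (a == 0) return(0)
  r2sum <- vapply(seq_along(regions), function(r) {
    sel <- structure$segment %in% regions[[r]]
    ax <- axes[[r]]
    u <- ax$direction / sqrt(sum(ax$direction^2))
    rel <- sweep(co[sel, , drop = FALSE], 2, ax$point)
    perp <- rel - outer(as.vector(rel %*% u), u)
    sum(rowSums(perp^2))
  }, numeric(1))
  if (length(regions) == 1) {
    return(2 * sqrt(r2sum / M) * 4 * (1 - cos(a / 4)) / a)
  }
  R <- length(regions)
  bases <- c(2, 3, 5, 7, 11)[seq_len(R)]
  th <- sapply(bases, function(b) (halton(n_quad, b) - 0.5) * a)
  msd <- sapply(seq_len(R), function(r) 4 * sin(th[, r] / 2)^2 * r2sum[r])
  mean(sqrt(rowSums(msd) / M))
}

#' Calibrate the rotation range to a target mean RMSD
#'
#' Solves for the full angle range (degrees) whose expected mean
#' per-particle atomic RMSD equals `target_rmsd_A` on this geometry.
#'
#' @param structure,regions,axes As in [simulate_motion()].
#' @param target_rmsd_A Target mean RMSD in Angstrom.
#' @return Angle range in degrees.
#' @export
calibrate_angle_range <- function(structure, regions, axes, target_rmsd_A) {
  f <- function(a) {
    expected_motion_rmsd(structure, regions, axes, a) - target_rmsd_A
  }
  if (f(179) < 0) stop("target RMSD unreachable with rotations < 180 deg")
  uniroot(f, c(1e-3, 179), tol = 1e-4)$root
}

#' Render a particle stack with CTF and noise
#'
#' Orientations are drawn quasi-uniformly over SO(3)
#' ([quasi_uniform_rotations()]); each particle's present/moved atoms are
#' splatted as small Gaussians through the analytic Fourier model,
#' modulated by a CTF with defocus uniform over `defocus_range`, and
#' white Gaussian noise is added so that (signal variance)/(noise
#' variance) equals `snr`. The pixel size is the structure box divided by
#' `D`.
#'
#' @param sim A `comp_simulation` or `motion_simulation`.
#' @param D Image size in pixels.
#' @param snr Signal-to-noise ratio (`Inf` for noise-free).
#' @param defocus_range Length-2 defocus range in micrometres.
#' @param seed Integer seed.
#' @param voltage,cs,amplitude_contrast Microscope parameters.
#' @param atom_sigma_px Splat width in pixels.
#' @return A `particle_stack`: `images` (D x D x n array), `metadata`
#'   tibble (orientations, shifts, CTF), `pixel_size`, and the simulation
#'   object as ground truth.
#' @export
render_particles <- function(sim, D = 64, snr = 0.1,
                             defocus_range = c(1, 2), seed = 1,
                             voltage = 300, cs = 2.7,
                             amplitude_contrast = 0.1,
                             atom_sigma_px = 1.6) {
  n <- sim$n_particles
  box_A <- box_size(sim$structure)
  pixel_size <- box_A / D
  quats <- quasi_uniform_rotations(n, seed = seed)
  set.seed(seed + 1)
  defocus <- runif(n, defocus_range[1], defocus_range[2])
  g <- freq_grid(D)
  full_mask <- list(idx = seq_along(g$kx), kx = as.vector(g$kx),
                    ky = as.vector(g$ky), k2 = as.vector(g$k2), D = D)
  sigma_box <- atom_sigma_px / D
  images <- array(0, c(D, D, n))
  set.seed(seed + 2)
  for (i in seq_len(n)) {
    pc <- particle_coords(sim, i)
    cb <- pc$coords / box_A
    Rm <- quat_to_matrix(quats[i, ])
    fw <- project_particle(cb, pc$weights, rep(sigma_box, nrow(cb)), Rm,
                           c(0, 0), full_mask)
    ctf <- ctf_params(defocus = defocus[i], voltage = voltage, cs = cs,
                      amplitude_contrast = amplitude_contrast,
                      pixel_size = pixel_size)
    fh <- matrix(fw$F, D / 2 + 1, D) * ctf_eval(ctf, g$k2, D)
    img <- image_from_fourier(fh)
    if (is.finite(snr)) {
      noise_sd <- stats::sd(img) / sqrt(snr)
      img <- img + matrix(rnorm(D * D, sd = noise_sd), D, D)
    }
    images[, , i] <- img
  }
  eul <- t(apply(quats, 1, quat_to_euler))
  metadata <- tibble::tibble(
    particle = seq_len(n),
    rot = eul[, 1], tilt = eul[, 2], psi = eul[, 3],
    shift_x = 0, shift_y = 0,
    defocus = defocus, voltage = voltage, cs = cs,
    amplitude_contrast = amplitude_contrast, b_factor = 0,
    pixel_size = pixel_size)
  structure(list(images = images, metadata = metadata,
                 pixel_size = pixel_size, D = D, snr = snr,
                 ground_truth = sim),
            class = "particle_stack")
}

#' @export
print.particle_stack <- function(x, ...) {
  cat(sprintf("<particle_stack> %d particles, %dx%d px, %.2f A/px, snr %s\n",
              dim(x$images)[3], x$D, x$D, x$pixel_size,
              format(x$snr)))
  invisible(x)
}
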