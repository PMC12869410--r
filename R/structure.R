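#' Segmented atomic (or pseudo-atomic) structure
#'
#' A structure is a tibble of points with columns `x`, `y`, `z`
#' (Angstrom, origin at the box centre), `segment` (integer label,
#' 0-based; segment 0 is the core in compositional simulations) and
#' `weight` (positive mass, e.g. atomic weight or 1), carrying the box
#' edge length as the `box_size_A` attribute. The box must enclose all
#' coordinates and every segment must be non-empty.
#'
#' @param coords M x 3 numeric matrix of coordinates in Angstrom.
#' @param segments Integer vector of segment labels in `0 .. K-1`.
#' @param weights Positive point weights (default 1).
#' @param box_size_A Box edge in Angstrom; default 2.2x the largest
#'   coordinate radius.
#' @return A `ptgmm_structure` tibble.
#' @export
protein_structure <- function(coords, segments = rep(0L, nrow(coords)),
                              weights = rep(1, nrow(coords)),
                              box_size_A = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) >= 1, all(is.finite(coords)),
            length(segments) == nrow(coords), all(weights > 0))
  segments <- as.integer(segments)
  K <- max(segments) + 1L
  if (!all(sort(unique(segments)) == 0:(K - 1))) {
    stop("segment labels must cover 0 .. K-1 with every segment non-empty")
  }
  rmax <- max(abs(coords))
  if (is.null(box_size_A)) box_size_A <- 2.2 * max(rmax, 1)
  if (box_size_A < 2 * rmax) {
    stop("box_size_A does not enclose all coordinates")
  }
  out <- tibble::tibble(x = coords[, 1], y = coords[, 2], z = coords[, 3],
                        segment = segments, weight = as.numeric(weights))
  attr(out, "box_size_A") <- box_size_A
  class(out) <- c("ptgmm_structure", class(out))
  out
}

#' @export
print.ptgmm_structure <- function(x, ...) {
  cat(sprintf("<ptgmm_structure> %d points, %d segments, box %.1f A\n",
              nrow(x), length(unique(x$segment)), attr(x, "box_size_A")))
  NextMethod()
}

structure_coords <- function(structure) {
  cbind(structure$x, structure$y, structure$z)
}

box_size <- function(structure) attr(structure, "box_size_A")

# Coordinates in box-normalized units (fractions of the box edge).
structure_coords_box <- function(structure) {
  structure_coords(structure) / box_size(structure)
}

#' Read a segmented structure from a PDB file
#'
#' Atom coordinates are recentred on their centre of mass. Segments come
#' from a chain-to-segment mapping table; unmapped chains go to segment 0.
#'
#' @param path PDB file path.
#' @param chain_segments Optional named integer vector mapping chain IDs to
#'   segment labels.
#' @param box_size_A Optional box edge override (Angstrom).
#' @return A [protein_structure()].
#' @export
read_structure <- function(path, chain_segments = NULL, box_size_A = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("read_structure() requires the bio3d package")
  }
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  coords <- cbind(at$x, at$y, at$z)
  coords <- sweep(coords, 2, colMeans(coords))
  segs <- rep(0L, nrow(coords))
  if (!is.null(chain_segments)) {
    hit <- match(at$chain, names(chain_segments))
    segs[!is.na(hit)] <- as.integer(chain_segments[hit[!is.na(hit)]])
  }
  protein_structure(coords, segs, box_size_A = box_size_A)
}
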