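#' Write an image stack as MRC/MRCS (mode 2)
#'
#' MRC2014, mode 2 (32-bit float), little-endian, with the voxel size
#' recorded in the cell dimensions. Images are written in column order
#' (x fastest), one section per particle.
#'
#' @param images D x D x n array (or D x D matrix for a single image).
#' @param path Output path.
#' @param pixel_size Pixel size in Angstrom.
#' @export
write_mrcs <- function(images, path, pixel_size = 1) {
  if (length(dim(images)) == 2) dim(images) <- c(dim(images), 1)
  d <- dim(images)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4,
                             endian = "little")
  wi(d)                                  # nx ny nz
  wi(2)                                  # mode 2 = float32
  wi(c(0, 0, 0))                         # nxstart
  wi(d)                                  # mx my mz
  wf(d * pixel_size)                     # cella
  wf(c(90, 90, 90))                      # cellb
  wi(c(1, 2, 3))                         # mapc mapr maps
  wf(c(min(images), max(images), mean(images)))
  wi(0)                                  # ispg
  wi(0)                                  # nsymbt
  writeBin(raw(100), con)                # extra
  wf(c(0, 0, 0))                         # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)  # machst little-endian
  wf(stats::sd(images))                  # rms
  wi(0)                                  # nlabl
  writeBin(raw(800), con)                # labels
  writeBin(as.numeric(images), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC/MRCS stack written in mode 2
#'
#' @param path File path.
#' @return List with `images` (nx x ny x nz array) and `pixel_size`.
#' @export
read_mrcs <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024) stop("not an MRC file (shorter than header)")
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop(sprintf("unsupported MRC mode %d (only mode 2)", mode))
  ri(3); mxyz <- ri(3)
  cella <- rf(3)
  seek(con, 1024)
  nvox <- prod(d)
  if (sz < 1024 + 4 * nvox) {
    stop(sprintf("truncated MRC file: %d voxels declared, %d bytes present",
                 nvox, sz - 1024))
  }
  data <- readBin(con, "numeric", nvox, size = 4, endian = "little")
  list(images = array(data, d),
       pixel_size = if (mxyz[1] > 0) cella[1] / mxyz[1] else 1)
}

star_columns <- c(
  rot = "_rlnAngleRot", tilt = "_rlnAngleTilt", psi = "_rlnAnglePsi",
  shift_x = "_rlnOriginX", shift_y = "_rlnOriginY",
  defocus = "_rlnDefocusU", voltage = "_rlnVoltage",
  cs = "_rlnSphericalAberration",
  amplitude_contrast = "_rlnAmplitudeContrast",
  b_factor = "_rlnCtfBfactor", pixel_size = "_rlnImagePixelSize")

#' Write particle metadata as a STAR table
#'
#' Orientations are intrinsic ZYZ Euler angles in degrees (see
#' [euler_to_matrix()]); shifts in pixels; CTF columns as in
#' [ctf_params()]. Extra columns are written with `_ptgmm` prefixes so a
#' round trip preserves everything.
#'
#' @param metadata Tibble as produced by [render_particles()].
#' @param path Output path.
#' @export
write_star <- function(metadata, path) {
  cols <- names(metadata)
  star_names <- ifelse(cols %in% names(star_columns),
                       star_columns[cols], paste0("_ptgmm", cols))
  lines <- c("", "data_particles", "", "loop_",
             sprintf("%s #%d", star_names, seq_along(cols)))
  vals <- vapply(seq_len(nrow(metadata)), function(i) {
    paste(vapply(cols, function(cn) {
      v <- metadata[[cn]][i]
      if (is.numeric(v)) sprintf("%.10g", v) else as.character(v)
    }, character(1)), collapse = "  ")
  }, character(1))
  writeLines(c(lines, vals, ""), path)
  invisible(path)
}

#' Read a STAR particle table written by [write_star()]
#'
#' @param path File path.
#' @param require_ctf Insist on orientation + CTF columns, naming any
#'   that are missing.
#' @return A metadata tibble with package column names.
#' @export
read_star <- function(path, require_ctf = TRUE) {
  lines <- readLines(path)
  li <- which(trimws(lines) == "loop_")
  if (!length(li)) stop("no loop_ block found in STAR file")
  i <- li[1] + 1
  star_names <- character()
  while (i <= length(lines) && startsWith(trimws(lines[i]), "_")) {
    star_names <- c(star_names, sub("\\s+#\\d+\\s*$", "", trimws(lines[i])))
    i <- i + 1
  }
  rows <- trimws(lines[i:length(lines)])
  rows <- rows[nzchar(rows)]
  mat <- do.call(rbind, strsplit(rows, "\\s+"))
  rev_map <- setNames(names(star_columns), star_columns)
  cols <- ifelse(star_names %in% names(rev_map), rev_map[star_names],
                 sub("^_ptgmm", "", star_names))
  out <- tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE),
                           .name_repair = "minimal")
  names(out) <- cols
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::everything(),
    function(v) {
      nv <- suppressWarnings(as.numeric(v))
      if (all(!is.na(nv))) nv else v
    }))
  if (require_ctf) {
    need <- c("rot", "tilt", "psi", "defocus", "voltage", "cs",
              "amplitude_contrast", "pixel_size")
    miss <- setdiff(need, names(out))
    if (length(miss)) {
      stop(sprintf("missing mandatory metadata column(s): %s",
                   paste(star_columns[miss], collapse = ", ")))
    }
  }
  out
}

#' Save a particle stack (images, metadata, ground truth)
#'
#' Writes `<prefix>.mrcs`, `<prefix>.star` and a ground-truth sidecar
#' `<prefix>_gt.tsv`, plus a provenance JSON.
#'
#' @param stack A [render_particles()] stack.
#' @param prefix Output path prefix.
#' @param seed Seed recorded in the provenance file.
#' @export
write_particle_stack <- function(stack, prefix, seed = NA) {
  write_mrcs(stack$images, paste0(prefix, ".mrcs"), stack$pixel_size)
  write_star(stack$metadata, paste0(prefix, ".star"))
  gt <- tidy(stack$ground_truth)
  utils::write.table(gt, paste0(prefix, "_gt.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_provenance(paste0(prefix, "_provenance.json"),
                   list(kind = class(stack$ground_truth)[1],
                        n_particles = nrow(stack$metadata),
                        D = stack$D, snr = stack$snr, seed = seed))
  invisible(prefix)
}

write_provenance <- function(path, config) {
  config$package_version <- as.character(utils::packageVersion("ptgmm"))
  config$config_hash <- rlang::hash(config)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' One archive holding all parameter arrays plus a configuration hash
#' that [infer()] can verify against a dataset.
#'
#' @param model A `ptgmm_model`.
#' @param path Checkpoint path.
#' @export
write_checkpoint <- function(model, path) {
  model$config_hash <- rlang::hash(list(model$model_config,
                                        model$prep_config))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "ptgmm_model")) stop("not a ptgmm checkpoint")
  m
}
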