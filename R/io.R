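#' Save a TVI sequence to an HDF5 container
#'
#' The container holds one 3D dataset named `velocity` plus scalar attributes
#' `pixel_pitch_mm`, `sample_rate_hz`, `domain_label` and (when present)
#' `seed`. Values are stored in double precision, so load/save round-trips
#' bit-exactly.
#'
#' @param seq a `tvi_sequence`.
#' @param path output file path; parent directory must exist.
#' @param overwrite overwrite an existing file (default FALSE).
#' @export
save_tvi <- function(seq, path, overwrite = FALSE) {
  stopifnot(inherits(seq, "tvi_sequence"))
  if (file.exists(path) && !overwrite)
    stop("file exists and overwrite = FALSE: ", path)
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  if (file.exists(path)) unlink(path)
  ok <- try(rhdf5::h5createFile(path), silent = TRUE)
  if (inherits(ok, "try-error") || !isTRUE(ok))
    stop("cannot create HDF5 file at ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(seq$velocity, path, "velocity")
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "velocity")
  rhdf5::h5writeAttribute(seq$pixel_pitch_mm, did, "pixel_pitch_mm")
  rhdf5::h5writeAttribute(seq$sample_rate_hz, did, "sample_rate_hz")
  rhdf5::h5writeAttribute(seq$domain_label, did, "domain_label")
  if (!is.null(seq$seed)) rhdf5::h5writeAttribute(seq$seed, did, "seed")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Load a TVI sequence from an HDF5 container
#'
#' @param path file written by [save_tvi()] (dataset `velocity` + metadata
#'   attributes).
#' @return a `tvi_sequence`.
#' @export
load_tvi <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  if (!"velocity" %in% contents$name)
    stop("format error: missing dataset 'velocity' in ", path)
  v <- rhdf5::h5read(path, "velocity")
  if (length(dim(v)) != 3L)
    stop("format error: dataset 'velocity' must be 3D, got ",
         length(dim(v)), "D")
  at <- rhdf5::h5readAttributes(path, "velocity")
  for (key in c("pixel_pitch_mm", "sample_rate_hz", "domain_label")) {
    if (is.null(at[[key]]))
      stop("format error: missing attribute '", key, "' in ", path)
  }
  tvi_sequence(v,
               pixel_pitch_mm = as.numeric(at$pixel_pitch_mm),
               sample_rate_hz = as.numeric(at$sample_rate_hz),
               domain_label = as.character(at$domain_label),
               seed = if (is.null(at$seed)) NULL else as.integer(at$seed))
}
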