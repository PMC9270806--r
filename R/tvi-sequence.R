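#' TVI sequence container
#'
#' A tissue-velocity image (TVI) sequence is a real-valued 3D grid indexed
#' (depth row, lateral column, time frame). Depth row 1 is the most
#' superficial tissue. Raw grids carry velocities in mm/s; standardized grids
#' are unitless.
#'
#' @param velocity 3D numeric array (depth x lateral x frames), all finite.
#' @param pixel_pitch_mm positive spatial pixel pitch in mm (default
#'   40/128 mm, a 40x40 mm^2 field of view on a 128x128 grid).
#' @param sample_rate_hz positive frame rate in Hz (default 512).
#' @param domain_label one of "simulated", "experimental", "surrogate",
#'   "translated".
#' @param seed optional integer recording the seed that generated the data.
#' @return object of class `tvi_sequence`.
#' @export
tvi_sequence <- function(velocity, pixel_pitch_mm = 40 / 128,
                         sample_rate_hz = 512,
                         domain_label = c("simulated", "experimental",
                                          "surrogate", "translated"),
                         seed = NULL) {
  if (!is.array(velocity) || length(dim(velocity)) != 3L)
    stop("`velocity` must be a 3D array (depth x lateral x frames)")
  if (!all(is.finite(velocity)))
    stop("`velocity` contains non-finite values")
  if (!is.numeric(pixel_pitch_mm) || pixel_pitch_mm <= 0)
    stop("`pixel_pitch_mm` must be positive")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("`sample_rate_hz` must be positive")
  domain_label <- match.arg(domain_label)
  structure(list(velocity = velocity,
                 pixel_pitch_mm = as.numeric(pixel_pitch_mm),
                 sample_rate_hz = as.numeric(sample_rate_hz),
                 domain_label = domain_label,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "tvi_sequence")
}

#' @export
print.tvi_sequence <- function(x, ...) {
  d <- dim(x$velocity)
  cat(sprintf("<tvi_sequence> %dx%dx%d  pitch %.4f mm  %g Hz  %.3f s  [%s]\n",
              d[1], d[2], d[3], x$pixel_pitch_mm, x$sample_rate_hz,
              duration_s(x), x$domain_label))
  invisible(x)
}

#' Sequence duration in seconds
#' @param seq a `tvi_sequence`.
#' @export
duration_s <- function(seq) {
  stopifnot(inherits(seq, "tvi_sequence"))
  dim(seq$velocity)[3] / seq$sample_rate_hz
}

#' Standardize a sequence to zero mean and unit standard deviation
#'
#' Standardization is applied per sequence over all voxels (sequences are
#' processed independently at inference time). Metadata are unchanged.
#'
#' @param seq a `tvi_sequence` with nonzero voxel variance.
#' @return standardized `tvi_sequence`.
#' @export
standardize <- function(seq) {
  stopifnot(inherits(seq, "tvi_sequence"))
  v <- seq$velocity
  s <- sd(as.vector(v))
  if (!is.finite(s) || s < 1e-12 * max(1, abs(mean(v))) || s == 0)
    stop("degenerate variance: sequence is constant-valued, cannot standardize")
  seq$velocity <- (v - mean(v)) / s
  seq
}
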