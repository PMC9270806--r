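#' Frame-wise difference map
#'
#' Per-pixel absolute difference between a paired input and output frame
#' (signed mode available for diagnostics).
#'
#' @param input_frame,output_frame matrices of identical shape.
#' @param signed return the signed difference instead of the absolute value.
#' @return matrix of the same shape.
#' @export
difference_map <- function(input_frame, output_frame, signed = FALSE) {
  if (!identical(dim(input_frame), dim(output_frame)))
    stop("shape mismatch between frames")
  d <- output_frame - input_frame
  if (signed) d else abs(d)
}

#' Similarity map of a translated sequence
#'
#' Frame-wise absolute difference maps between the paired input (simulated)
#' and output (translated) sequences, aggregated over all frames. A low
#' value means the generator left that pixel unchanged. The default
#' aggregation is the mean; "sum" differs by the constant factor n_frames.
#'
#' @param input_seq,output_seq `tvi_sequence` objects of identical shape.
#' @param mode "mean" (default) or "sum".
#' @return matrix of class `similarity_map` with attributes `mode` and
#'   `pixel_pitch_mm`.
#' @export
similarity_map <- function(input_seq, output_seq, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  vx <- input_seq$velocity; vy <- output_seq$velocity
  if (!identical(dim(vx), dim(vy)))
    stop("shape mismatch between sequences")
  d <- dim(vx)
  D <- matrix(abs(vy - vx), d[1] * d[2], d[3])
  m <- if (mode == "mean") rowMeans(D) else rowSums(D)
  m <- matrix(m, d[1], d[2])
  attr(m, "mode") <- mode
  attr(m, "pixel_pitch_mm") <- input_seq$pixel_pitch_mm
  class(m) <- c("similarity_map", class(m))
  m
}

#' Similarity as a function of depth
#'
#' Per-depth-row mean of a similarity map, paired with depth in mm via the
#' pixel pitch (row 1 is the most superficial tissue).
#'
#' @param map a `similarity_map` (or plain matrix plus `pixel_pitch_mm`).
#' @param pixel_pitch_mm pitch override when `map` lacks the attribute.
#' @return data.frame with `depth_mm` and `similarity`.
#' @export
depth_profile <- function(map, pixel_pitch_mm = NULL) {
  pitch <- pixel_pitch_mm %||% attr(map, "pixel_pitch_mm")
  if (is.null(pitch)) stop("pixel pitch unknown; pass `pixel_pitch_mm`")
  data.frame(depth_mm = (seq_len(nrow(map)) - 0.5) * pitch,
             similarity = rowMeans(unclass(map)))
}
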