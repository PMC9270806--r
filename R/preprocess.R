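#' Preprocessing configuration for experimental-domain sequences
#'
#' @param band_hz bandpass corner frequencies in Hz, default c(5, 50).
#' @param butter_order Butterworth design order (MATLAB convention: the
#'   bandpass has `2 * butter_order` poles), default 4.
#' @param median_kernel_mm spatial median-filter kernel in mm, default c(1, 1).
#' @param target_shape target (rows, cols, frames), default c(128, 128, 1024).
#' @param target_rate_hz target frame rate, default 512.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(band_hz = c(5, 50), butter_order = 4,
                              median_kernel_mm = c(1, 1),
                              target_shape = c(128L, 128L, 1024L),
                              target_rate_hz = 512) {
  stopifnot(length(band_hz) == 2, band_hz[1] > 0, band_hz[1] < band_hz[2],
            butter_order >= 1, all(median_kernel_mm > 0),
            length(target_shape) == 3, all(target_shape >= 1),
            target_rate_hz > 0)
  structure(list(band_hz = band_hz, butter_order = as.integer(butter_order),
                 median_kernel_mm = median_kernel_mm,
                 target_shape = as.integer(target_shape),
                 target_rate_hz = target_rate_hz),
            class = "preprocess_config")
}

# Zero-phase (forward-backward) IIR filtering of every column of a T x P
# matrix, vectorized across pixels. Odd-symmetric edge padding (length npad)
# suppresses the start-up transients of the slow low-corner poles.
iir_filtfilt_matrix <- function(X, b, a, npad = 3L * (length(b) - 1L)) {
  T_ <- nrow(X)
  npad <- min(npad, T_ - 1L)
  if (npad > 0L) {
    head_ref <- 2 * rep(X[1L, ], each = npad) -
      X[seq(npad + 1L, 2L), , drop = FALSE]
    tail_ref <- 2 * rep(X[T_, ], each = npad) -
      X[seq(T_ - 1L, T_ - npad), , drop = FALSE]
    X <- rbind(head_ref, X, tail_ref)
  }
  apply_once <- function(M) {
    p <- length(b)
    Mp <- rbind(matrix(0, p - 1, ncol(M)), M)
    y <- stats::filter(Mp, b, method = "convolution", sides = 1)
    y <- y[-seq_len(p - 1), , drop = FALSE]
    if (length(a) > 1)
      y <- stats::filter(y, -a[-1], method = "recursive")
    matrix(as.numeric(y), nrow(M), ncol(M))
  }
  rev_rows <- function(M) M[rev(seq_len(nrow(M))), , drop = FALSE]
  Y <- rev_rows(apply_once(rev_rows(apply_once(X))))
  if (npad > 0L) Y <- Y[npad + seq_len(T_), , drop = FALSE]
  Y
}

# Butterworth bandpass design for a given sample rate.
bandpass_design <- function(cfg, sample_rate_hz) {
  nyq <- sample_rate_hz / 2
  if (cfg$band_hz[2] >= nyq)
    stop("bandpass edge ", cfg$band_hz[2], " Hz is at or above Nyquist (",
         nyq, " Hz)")
  bf <- signal::butter(cfg$butter_order, cfg$band_hz / nyq, type = "pass")
  list(b = as.numeric(bf$b), a = as.numeric(bf$a))
}

#' Frequency response magnitude of the designed bandpass
#'
#' @param cfg a [preprocess_config()].
#' @param sample_rate_hz sample rate the filter is designed for.
#' @param freq_hz frequencies at which to evaluate.
#' @return magnitude |H(f)| of the single-pass design.
#' @export
bandpass_response <- function(cfg, sample_rate_hz, freq_hz) {
  d <- bandpass_design(cfg, sample_rate_hz)
  w <- 2 * pi * freq_hz / sample_rate_hz
  ew <- exp(-1i * outer(w, seq_along(d$b) - 1))
  H <- (ew %*% d$b) / (ew[, seq_along(d$a), drop = FALSE] %*% d$a)
  as.numeric(Mod(H))
}

#' Half-power (-3 dB) frequencies of the designed bandpass
#'
#' Located by bisection on the single-pass magnitude response.
#'
#' @inheritParams bandpass_response
#' @return numeric length-2: lower and upper half-power frequencies in Hz.
#' @export
bandpass_halfpower_hz <- function(cfg, sample_rate_hz = 512) {
  target <- sqrt(0.5)
  f_mid <- sqrt(prod(cfg$band_hz))
  lo <- stats::uniroot(function(f) bandpass_response(cfg, sample_rate_hz, f) - target,
                       c(1e-3, f_mid), tol = 1e-10)$root
  hi <- stats::uniroot(function(f) bandpass_response(cfg, sample_rate_hz, f) - target,
                       c(f_mid, sample_rate_hz / 2 - 1e-6), tol = 1e-10)$root
  c(lo, hi)
}

#' Temporal Butterworth bandpass of every pixel's time signal
#'
#' 4th-order Butterworth bandpass (5-50 Hz by default), applied zero-phase
#' (forward-backward) so per-pixel signals stay lag-free.
#'
#' @param seq a `tvi_sequence`.
#' @param cfg a [preprocess_config()].
#' @return filtered `tvi_sequence`.
#' @export
bandpass_temporal <- function(seq, cfg = preprocess_config()) {
  stopifnot(inherits(seq, "tvi_sequence"))
  d <- dim(seq$velocity)
  des <- bandpass_design(cfg, seq$sample_rate_hz)
  if (d[3] < 3 * length(des$a))
    stop("sequence too short for filter edge handling")
  X <- t(matrix(seq$velocity, d[1] * d[2], d[3]))
  # pad by about two periods of the lowest passband frequency
  npad <- as.integer(min(d[3] - 1, ceiling(2 * seq$sample_rate_hz / cfg$band_hz[1])))
  Y <- iir_filtfilt_matrix(X, des$b, des$a, npad = npad)
  seq$velocity <- array(t(Y), d)
  seq
}

# mm -> px kernel size: nearest odd integer >= 3.
median_kernel_px <- function(kernel_mm, pitch_mm) {
  r <- kernel_mm / pitch_mm
  k <- 2L * as.integer(round((r - 1) / 2)) + 1L
  max(k, 3L)
}

#' Per-frame 2D median filtering
#'
#' The kernel size in mm is converted to the nearest odd pixel count (at
#' least 3; 3x3 at the default 0.3125 mm pitch).
#'
#' @param seq a `tvi_sequence`.
#' @param cfg a [preprocess_config()].
#' @return filtered `tvi_sequence`.
#' @export
median_filter_spatial <- function(seq, cfg = preprocess_config()) {
  stopifnot(inherits(seq, "tvi_sequence"))
  k <- median_kernel_px(cfg$median_kernel_mm[1], seq$pixel_pitch_mm)
  d <- dim(seq$velocity)
  v <- seq$velocity
  for (f in seq_len(d[3]))
    v[, , f] <- cpp_median2d(v[, , f], k)
  seq$velocity <- v
  seq
}

# Cubic-spline interpolation matrix mapping n_in uniformly spaced samples
# (cell centers on [0, 1]) to n_out. Cached per size pair.
spline_matrix <- function(n_in, n_out) {
  key <- paste0("spl_", n_in, "_", n_out)
  hit <- .tvigan_env[[key]]
  if (!is.null(hit)) return(hit)
  x_in <- (seq_len(n_in) - 0.5) / n_in
  x_out <- (seq_len(n_out) - 0.5) / n_out
  A <- matrix(0, n_out, n_in)
  for (j in seq_len(n_in)) {
    e <- numeric(n_in); e[j] <- 1
    A[, j] <- splinefun(x_in, e, method = "fmm")(x_out)
  }
  .tvigan_env[[key]] <- A
  A
}

#' Downsample a sequence to a target shape and rate
#'
#' Spatial axes use bicubic spline interpolation per frame; the temporal axis
#' is low-pass filtered (zero-phase windowed-sinc anti-alias when the rate is
#' reduced) and then cubic-spline resampled to the target frame count.
#'
#' @param seq a `tvi_sequence`.
#' @param cfg a [preprocess_config()] with `target_shape`/`target_rate_hz` at
#'   or below the source sizes.
#' @return resampled `tvi_sequence` with updated metadata.
#' @export
resample_sequence <- function(seq, cfg = preprocess_config()) {
  stopifnot(inherits(seq, "tvi_sequence"))
  d <- dim(seq$velocity)
  tgt <- cfg$target_shape
  if (any(tgt > d) || cfg$target_rate_hz > seq$sample_rate_hz)
    stop("upsampling requested: target exceeds source shape or rate; ",
         "only downsampling is supported")
  v <- seq$velocity
  if (identical(as.integer(d), as.integer(tgt)) &&
      isTRUE(all.equal(cfg$target_rate_hz, seq$sample_rate_hz)))
    return(seq)
  d_orig <- d
  # spatial axes
  if (tgt[1] != d[1]) {
    A <- spline_matrix(d[1], tgt[1])
    v <- array(A %*% matrix(v, d[1], d[2] * d[3]), c(tgt[1], d[2], d[3]))
    d <- dim(v)
  }
  if (tgt[2] != d[2]) {
    A <- spline_matrix(d[2], tgt[2])
    vp <- aperm(v, c(2, 1, 3))
    vp <- array(A %*% matrix(vp, d[2], d[1] * d[3]), c(tgt[2], d[1], d[3]))
    v <- aperm(vp, c(2, 1, 3))
    d <- dim(v)
  }
  # temporal axis
  if (cfg$target_rate_hz < seq$sample_rate_hz || tgt[3] != d[3]) {
    X <- t(matrix(v, d[1] * d[2], d[3]))   # T x P
    ratio <- cfg$target_rate_hz / seq$sample_rate_hz
    if (ratio < 1) {
      ntap <- 65L
      bf <- signal::fir1(ntap - 1L, 0.9 * ratio)
      half <- (ntap - 1L) %/% 2L
      Xp <- rbind(matrix(0, half, ncol(X)), X, matrix(0, half, ncol(X)))
      Xf <- stats::filter(Xp, bf, method = "convolution", sides = 2)
      X <- matrix(as.numeric(Xf[half + seq_len(d[3]), ]), d[3], ncol(X))
    }
    Ct <- spline_matrix(d[3], tgt[3])
    X <- Ct %*% X
    v <- array(t(X), c(d[1], d[2], tgt[3]))
  }
  seq$velocity <- v
  # the physical field of view is unchanged: coarser grid, larger pitch
  seq$pixel_pitch_mm <- seq$pixel_pitch_mm * d_orig[1] / tgt[1]
  seq$sample_rate_hz <- cfg$target_rate_hz
  seq
}

#' Full experimental-domain conditioning chain
#'
#' Bandpass (temporal) -> median filter (spatial) -> bicubic downsampling,
#' in that order; the domain label is preserved. Standardization is applied
#' separately before training via [standardize()].
#'
#' @param seq raw `tvi_sequence` with metadata.
#' @param cfg a [preprocess_config()].
#' @return conditioned `tvi_sequence`.
#' @export
preprocess_experimental <- function(seq, cfg = preprocess_config()) {
  out <- bandpass_temporal(seq, cfg)
  out <- median_filter_spatial(out, cfg)
  resample_sequence(out, cfg)
}
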