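#' Log-transformed variance map of a sequence
#'
#' Per-pixel temporal variance, log-transformed (natural log, with an epsilon
#' floor guarding zero-variance pixels) to suppress high-amplitude peaks of
#' motor-unit activations while retaining the spatial texture.
#'
#' @param seq a `tvi_sequence` with at least 2 frames.
#' @param epsilon variance floor added before the log (default 1e-12).
#' @return matrix (rows x cols) of class `variance_map` with attributes
#'   `epsilon` and `pixel_pitch_mm`.
#' @export
variance_map <- function(seq, epsilon = 1e-12) {
  stopifnot(inherits(seq, "tvi_sequence"))
  if (dim(seq$velocity)[3] < 2)
    stop("variance map needs at least 2 frames")
  m <- log(pixel_variance(seq$velocity) + epsilon)
  attr(m, "epsilon") <- epsilon
  attr(m, "pixel_pitch_mm") <- seq$pixel_pitch_mm
  class(m) <- c("variance_map", class(m))
  m
}

shared_histogram <- function(map1, map2, n_bins) {
  x <- as.vector(map1); y <- as.vector(map2)
  rng <- range(c(x, y))
  if (diff(rng) <= 0)
    stop("degenerate histograms: all values identical")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  cnt <- function(v) tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                           all.inside = TRUE), n_bins)
  list(p = cnt(x), q = cnt(y))
}

#' Histogram correlation and Bhattacharyya distance between two maps
#'
#' Both maps are binned on a shared grid over the pooled value range.
#' `Corr` is the Pearson correlation of the bin counts; `DBhat` is the
#' Hellinger-form Bhattacharyya distance
#' `sqrt(1 - sum(sqrt(p_i * q_i)))` of the normalized histograms.
#'
#' @param map1,map2 numeric matrices in the same units.
#' @param n_bins number of shared bins (default 64).
#' @return list with `Corr` and `DBhat` (`Corr` is NA when one histogram is
#'   perfectly flat, where a Pearson correlation is undefined).
#' @export
histogram_features <- function(map1, map2, n_bins = 64L) {
  h <- shared_histogram(map1, map2, n_bins)
  if (sum(h$p > 0) < 2 || sum(h$q > 0) < 2)
    stop("degenerate histograms: all mass in a single bin")
  p <- h$p / sum(h$p); q <- h$q / sum(h$q)
  bc <- sum(sqrt(p * q))
  corr <- if (sd(h$p) == 0 || sd(h$q) == 0) NA_real_
          else cor(h$p, h$q)
  list(Corr = corr, DBhat = sqrt(max(0, 1 - min(bc, 1))))
}

# Valid-mode 2D windowed filtering built on the package's gather kernels.
filter2_valid <- function(m, w) {
  k <- dim(w)
  nb <- nb_cache_get(c(dim(m), 1L), c(k, 1L), c(1L, 1L, 1L), c(0L, 0L, 0L),
                     c(0L, 0L, 0L), FALSE)
  out <- matrix(as.vector(w), 1L) %*% cpp_im2col(matrix(as.vector(m), 1L), nb)
  matrix(out, attr(nb, "out_dims")[1], attr(nb, "out_dims")[2])
}

# Standard SSIM (Gaussian window, default constants) between two equally
# shaped nonnegative images.
ssim2d <- function(x, y, win_size = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  stopifnot(identical(dim(x), dim(y)))
  win_size <- min(win_size, dim(x) - (dim(x) + 1) %% 2)
  if (win_size < 3) stop("maps too small for the SSIM window")
  g <- exp(-(seq_len(win_size) - (win_size + 1) / 2)^2 / (2 * sigma^2))
  w <- outer(g, g); w <- w / sum(w)
  L <- diff(range(c(x, y)))
  if (L <= 0) return(1)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  f <- function(m) filter2_valid(m, w)
  mx <- f(x); my <- f(y)
  sxx <- f(x * x) - mx * mx
  syy <- f(y * y) - my * my
  sxy <- f(x * y) - mx * my
  ss <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  mean(ss)
}

#' K-space structural similarity of two variance maps
#'
#' Each map is 2D Fourier transformed; the strictly positive-frequency
#' quadrant (kx > 0 and ky > 0, excluding DC and Nyquist) is retained, its
#' magnitude log-compressed (log(1 + |F|)), and the standard SSIM
#' (luminance/contrast/structure, Gaussian window) computed between the two
#' quadrants.
#'
#' @param map1,map2 matrices of identical shape.
#' @return SSIM value in [-1, 1].
#' @export
kspace_ssim <- function(map1, map2) {
  if (!identical(dim(map1), dim(map2)))
    stop("shape mismatch between maps")
  quad <- function(m) {
    F <- fft(unclass(m))
    d <- dim(F)
    log1p(Mod(F[2:(d[1] %/% 2), 2:(d[2] %/% 2), drop = FALSE]))
  }
  ssim2d(quad(map1), quad(map2))
}

# Welch average power spectral density over all pixels of a sequence.
welch_avg_psd <- function(seq, nperseg = 256L, overlap = 0.5) {
  v <- seq$velocity
  d <- dim(v)
  X <- t(matrix(v, d[1] * d[2], d[3]))          # T x P
  nper <- min(nperseg, d[3])
  step <- max(1L, floor(nper * (1 - overlap)))
  starts <- seq(1L, d[3] - nper + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  U <- sum(win^2) * seq$sample_rate_hz
  nf <- nper %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- X[s:(s + nper - 1L), , drop = FALSE]
    seg <- seg - rep(colMeans(seg), each = nper)
    seg <- seg * win
    P <- Mod(mvfft(seg))^2 / U
    acc <- acc + rowMeans(P[seq_len(nf), , drop = FALSE])
  }
  psd <- acc / length(starts)
  psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]      # one-sided
  list(freq_hz = (seq_len(nf) - 1L) * seq$sample_rate_hz / nper, psd = psd)
}

#' Correlation of average log power spectral densities
#'
#' The Psd of a sequence is the average of the per-pixel Welch Psds; the
#' metric is the Pearson correlation of the two log-transformed average Psds
#' over the shared frequency grid.
#'
#' @param seqA,seqB `tvi_sequence` objects with equal sample rates.
#' @param nperseg Welch segment length (default 256, clamped to the sequence
#'   length).
#' @param overlap Welch segment overlap fraction (default 0.5).
#' @return correlation in [-1, 1].
#' @export
psd_correlation <- function(seqA, seqB, nperseg = 256L, overlap = 0.5) {
  if (!isTRUE(all.equal(seqA$sample_rate_hz, seqB$sample_rate_hz)))
    stop("sequences must share the sample rate")
  nper <- min(nperseg, dim(seqA$velocity)[3], dim(seqB$velocity)[3])
  pa <- welch_avg_psd(seqA, nper, overlap)
  pb <- welch_avg_psd(seqB, nper, overlap)
  cor(log(pa$psd + 1e-300), log(pb$psd + 1e-300))
}

#' Content consistency between paired input and translated sequences
#'
#' Per retained pixel (temporal variance above 1% of the input's median
#' pixel variance), the normalized cross-correlation between the input and
#' translated time signals is computed; the maximal correlation and its lag
#' (in ms) are recorded, and their mean and standard deviation across pixels
#' reported. The lag search is bounded (default +/-250 ms).
#'
#' @param input_seq,translated_seq `tvi_sequence` objects of the same shape
#'   and rate.
#' @param max_lag_ms lag search bound in ms.
#' @return list with `xcorr_mean`, `xcorr_sd`, `lag_ms_mean`, `lag_ms_sd`,
#'   `n_pixels`.
#' @export
content_consistency <- function(input_seq, translated_seq, max_lag_ms = 250) {
  vx <- input_seq$velocity; vy <- translated_seq$velocity
  if (!identical(dim(vx), dim(vy)))
    stop("shape mismatch between input and translated sequences")
  if (!isTRUE(all.equal(input_seq$sample_rate_hz,
                        translated_seq$sample_rate_hz)))
    stop("sequences must share the sample rate")
  d <- dim(vx)
  fs <- input_seq$sample_rate_hz
  X <- t(matrix(vx, d[1] * d[2], d[3]))
  Y <- t(matrix(vy, d[1] * d[2], d[3]))
  varx <- apply(X, 2, var)
  keep <- which(varx > 0.01 * median(varx) & apply(Y, 2, var) > 0)
  if (!length(keep)) stop("no pixels retained for content comparison")
  X <- X[, keep, drop = FALSE]; Y <- Y[, keep, drop = FALSE]
  X <- X - rep(colMeans(X), each = d[3])
  Y <- Y - rep(colMeans(Y), each = d[3])
  L <- min(as.integer(floor(max_lag_ms / 1000 * fs)), d[3] - 1L)
  nfft <- nextn(d[3] + L + 1L, 2)
  FX <- mvfft(rbind(X, matrix(0, nfft - d[3], ncol(X))))
  FY <- mvfft(rbind(Y, matrix(0, nfft - d[3], ncol(Y))))
  CC <- Re(mvfft(Conj(FX) * FY, inverse = TRUE)) / nfft
  # row k+1 is sum_t x_t y_(t+k); negative lags wrap to the tail
  lags <- c(0:L, -(L:1))
  rows <- c(seq_len(L + 1L), nfft - (L:1) + 1L)
  W <- CC[rows, , drop = FALSE]
  norm <- sqrt(colSums(X^2) * colSums(Y^2))
  W <- W / rep(norm, each = nrow(W))
  best <- max.col(t(W), ties.method = "first")
  xc <- W[cbind(best, seq_along(best))]
  lag_ms <- lags[best] * 1000 / fs
  list(xcorr_mean = mean(xc), xcorr_sd = sd(xc),
       lag_ms_mean = mean(lag_ms), lag_ms_sd = sd(lag_ms),
       n_pixels = length(keep))
}

#' Cross-compare two sequence sets with the full metric battery
#'
#' Spatial (variance-map histogram correlation, Bhattacharyya distance,
#' K-space SSIM) and temporal (Psd correlation) features are computed over
#' all |X| x |Y| ordered pairs; the paired content metrics (xCorr, lag) are
#' computed only when `paired = TRUE`, pairing `setX[[i]]` with `setY[[i]]`.
#'
#' @param setX,setY nonempty lists of `tvi_sequence` objects.
#' @param paired also compute xCorr/lag over index-matched pairs (requires
#'   equal set sizes).
#' @param n_bins histogram bins (default 64).
#' @param epsilon variance-map floor.
#' @param max_lag_ms lag bound for the content metrics.
#' @return object of class `feature_report`: per metric, `mean`, `sd` and
#'   `n_pairs`.
#' @export
cross_compare <- function(setX, setY, paired = FALSE, n_bins = 64L,
                          epsilon = 1e-12, max_lag_ms = 250) {
  if (!length(setX) || !length(setY)) stop("sets must be nonempty")
  if (paired && length(setX) != length(setY))
    stop("paired comparison requires equal set sizes")
  vmX <- lapply(setX, variance_map, epsilon = epsilon)
  vmY <- lapply(setY, variance_map, epsilon = epsilon)
  n <- length(setX) * length(setY)
  corr <- dbh <- ssi <- cpsd <- numeric(n)
  k <- 0L
  for (i in seq_along(setX)) {
    for (j in seq_along(setY)) {
      k <- k + 1L
      hf <- histogram_features(vmX[[i]], vmY[[j]], n_bins)
      corr[k] <- hf$Corr; dbh[k] <- hf$DBhat
      ssi[k] <- kspace_ssim(vmX[[i]], vmY[[j]])
      cpsd[k] <- psd_correlation(setX[[i]], setY[[j]])
    }
  }
  ms <- function(v) list(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0)
  rep_ <- list(DBhat = c(ms(dbh), n_pairs = n),
               Corr = c(ms(corr), n_pairs = n),
               SSI = c(ms(ssi), n_pairs = n),
               CorrPsd = c(ms(cpsd), n_pairs = n))
  if (paired) {
    cc <- lapply(seq_along(setX), function(i)
      content_consistency(setX[[i]], setY[[i]], max_lag_ms))
    xcm <- vapply(cc, `[[`, 0, "xcorr_mean")
    lgm <- vapply(cc, `[[`, 0, "lag_ms_mean")
    rep_$xCorr <- c(ms(xcm), n_pairs = length(setX))
    rep_$lag_ms <- c(ms(lgm), n_pairs = length(setX))
  }
  structure(rep_, class = "feature_report")
}

#' @export
print.feature_report <- function(x, ...) {
  cat("<feature_report>\n")
  for (m in names(x))
    cat(sprintf("  %-8s %8.4f +/- %.4f  (n = %d)\n", m, x[[m]]$mean,
                x[[m]]$sd, x[[m]]$n_pairs))
  invisible(x)
}

#' One-row data frame of a feature report (Table-style)
#'
#' @param x a `feature_report`.
#' @param ... unused.
#' @return data.frame with `<metric>_mean` / `<metric>_sd` columns.
#' @export
as.data.frame.feature_report <- function(x, ...) {
  cols <- unlist(lapply(names(x), function(m)
    stats::setNames(list(x[[m]]$mean, x[[m]]$sd),
                    paste0(m, c("_mean", "_sd")))), recursive = FALSE)
  as.data.frame(cols)
}
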