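#' Surrogate configuration for the in-vivo-like domain
#'
#' The surrogate stands in for non-deposited in vivo tissue-velocity data.
#' It reproduces the descriptive statistics used downstream: oscillatory
#' sources in the 8-20 Hz band, complex granular spatial texture with 1-2 mm
#' correlation length, and a quiet superficial (subcutaneous) layer. It makes
#' no claim of physiological fidelity; users with real TVI data bypass it via
#' [preprocess_experimental()].
#'
#' @param corr_length_mm texture correlation length (half-width at half
#'   maximum of the spatial autocorrelation), default 1.5 mm.
#' @param texture_contrast relative sd of the multiplicative texture field,
#'   default 0.5.
#' @param osc_band_hz source firing-rate band, default c(8, 20).
#' @param superficial_depth_mm depth of the attenuated superficial layer,
#'   default 5 mm.
#' @param attenuation multiplicative factor applied to the superficial layer,
#'   in [0, 1], default 0.15.
#' @param n_sources_range number of oscillatory sources, default c(6, 12).
#' @param source_diameter_range_mm source extent range, default c(3, 8).
#' @param noise_level background-noise sd relative to the signal sd,
#'   default 0.1.
#' @param grid,fov_mm,duration_s,sample_rate_hz geometry, matching the
#'   simulated domain defaults.
#' @param seed optional integer seed.
#' @return a `surrogate_config` list.
#' @export
surrogate_config <- function(corr_length_mm = 1.5, texture_contrast = 0.5,
                             osc_band_hz = c(8, 20),
                             superficial_depth_mm = 5, attenuation = 0.15,
                             n_sources_range = c(6L, 12L),
                             source_diameter_range_mm = c(3, 8),
                             noise_level = 0.1,
                             grid = c(128L, 128L), fov_mm = c(40, 40),
                             duration_s = 2, sample_rate_hz = 512,
                             seed = NULL) {
  stopifnot(corr_length_mm > 0, corr_length_mm < min(fov_mm),
            attenuation >= 0, attenuation <= 1,
            osc_band_hz[1] > 0, osc_band_hz[1] <= osc_band_hz[2],
            texture_contrast >= 0, noise_level >= 0)
  structure(list(corr_length_mm = corr_length_mm,
                 texture_contrast = texture_contrast,
                 osc_band_hz = osc_band_hz,
                 superficial_depth_mm = superficial_depth_mm,
                 attenuation = attenuation,
                 n_sources_range = as.integer(n_sources_range),
                 source_diameter_range_mm = source_diameter_range_mm,
                 noise_level = noise_level, grid = as.integer(grid),
                 fov_mm = fov_mm, duration_s = duration_s,
                 sample_rate_hz = sample_rate_hz, seed = seed),
            class = "surrogate_config")
}

# Dense Toeplitz matrix implementing 1D Gaussian smoothing with replicated
# mass (columns renormalized so a constant field stays constant).
gauss_band_matrix <- function(n, sigma_px) {
  x <- seq_len(n)
  K <- exp(-outer(x, x, "-")^2 / (2 * sigma_px^2))
  K / rowSums(K)
}

#' Granular texture modulation field
#'
#' A thresholded band-limited Gaussian random field: white noise smoothed to
#' the configured correlation length, rescaled to unit mean and the
#' configured contrast, clipped at zero ("holes"), and attenuated in the
#' superficial rows.
#'
#' @param cfg a [surrogate_config()].
#' @param seed integer seed.
#' @return 2D matrix (rows x cols), unit mean over the non-attenuated region.
#' @export
texture_field <- function(cfg = surrogate_config(), seed = NULL) {
  with_seed(seed, {
    h <- cfg$grid[1]; w <- cfg$grid[2]
    pitch <- cfg$fov_mm[1] / h
    # HWHM of the autocorrelation of a Gaussian-smoothed field is
    # sqrt(2 ln 2) * sqrt(2) * sigma_kernel
    sigma_px <- cfg$corr_length_mm / pitch / (sqrt(2 * log(2)) * sqrt(2))
    g <- matrix(rnorm(h * w), h, w)
    Kh <- gauss_band_matrix(h, sigma_px)
    Kw <- gauss_band_matrix(w, sigma_px)
    g <- Kh %*% g %*% t(Kw)
    g <- (g - mean(g)) / sd(g)
    field <- pmax(1 + cfg$texture_contrast * g, 0)
    sup_rows <- seq_len(min(h, floor(cfg$superficial_depth_mm / pitch)))
    deep <- setdiff(seq_len(h), sup_rows)
    # normalize to unit mean over the non-attenuated region (whole field when
    # the field of view lies entirely within the superficial layer)
    norm_rows <- if (length(deep)) deep else seq_len(h)
    field <- field / mean(field[norm_rows, ])
    field[sup_rows, ] <- field[sup_rows, ] * cfg$attenuation
    field
  })
}

#' Generate a raw surrogate TVI-like sequence
#'
#' Spatially extended twitch-train sources oscillating at 8-20 Hz are
#' superposed, multiplied by a granular [texture_field()], and overlaid with
#' spatially correlated background noise. Passing the result through
#' [preprocess_experimental()] and [standardize()] yields a domain-B training
#' example.
#'
#' @param cfg a [surrogate_config()].
#' @param seed integer seed.
#' @return raw `tvi_sequence` with `domain_label = "surrogate"`.
#' @export
generate_surrogate <- function(cfg = surrogate_config(), seed = NULL) {
  with_seed(seed, {
    h <- cfg$grid[1]; w <- cfg$grid[2]
    pitch <- cfg$fov_mm[1] / h
    nfr <- round(cfg$duration_s * cfg$sample_rate_hz)
    t_grid <- (seq_len(nfr) - 1) / cfg$sample_rate_hz
    dmm <- (seq_len(h) - 0.5) * pitch
    lmm <- (seq_len(w) - 0.5) * (cfg$fov_mm[2] / w)
    vm <- matrix(0, h * w, nfr)
    n_src <- sample(seq(cfg$n_sources_range[1], cfg$n_sources_range[2]), 1L)
    for (s in seq_len(n_src)) {
      cd <- runif(1, 0, cfg$fov_mm[1]); cl <- runif(1, 0, cfg$fov_mm[2])
      diam <- runif(1, cfg$source_diameter_range_mm[1],
                    cfg$source_diameter_range_mm[2])
      fr <- runif(1, cfg$osc_band_hz[1], cfg$osc_band_hz[2])
      sig <- diam / 4
      env <- exp(-outer((dmm - cd)^2, (lmm - cl)^2, "+") / (2 * sig^2))
      keep <- which(env > 0.01)
      if (!length(keep)) next
      times <- sample_firing_times(fr, cfg$duration_s, 0.2, 0.010)
      train <- twitch_train(times, t_grid, 0.025, 1)
      vm[keep, ] <- vm[keep, ] + outer(env[keep], train)
    }
    tex <- texture_field(cfg)
    vm <- vm * as.vector(tex)
    if (cfg$noise_level > 0) {
      amp <- cfg$noise_level * max(sd(as.vector(vm)), 1e-12)
      noise <- matrix(rnorm(h * w * nfr), h, w * nfr)
      sigma_px <- max(cfg$corr_length_mm / pitch / 2, 0.5)
      Kh <- gauss_band_matrix(h, sigma_px)
      Kw <- gauss_band_matrix(w, sigma_px)
      noise <- Kh %*% noise                              # depth smoothing
      noise <- array(noise, c(h, w, nfr))
      noise <- aperm(array(Kw %*% matrix(aperm(noise, c(2, 1, 3)), w, h * nfr),
                           c(w, h, nfr)), c(2, 1, 3))    # lateral smoothing
      noise <- noise / sd(as.vector(noise)) * amp
      vm <- vm + matrix(noise, h * w, nfr)
    }
    tvi_sequence(array(vm, c(h, w, nfr)), pixel_pitch_mm = pitch,
                 sample_rate_hz = cfg$sample_rate_hz,
                 domain_label = "surrogate", seed = seed)
  })
}

#' Generate a set of surrogate sequences
#'
#' @param n number of sequences.
#' @param cfg a [surrogate_config()].
#' @param seed integer seed; per-sequence seeds are derived from it.
#' @param out_dir optional output directory (HDF5 files `sur_%03d.h5`).
#' @param preprocess run [preprocess_experimental()] on each raw sequence
#'   (default TRUE).
#' @param pp_cfg preprocessing configuration; defaults to the surrogate's own
#'   geometry as target.
#' @param standardize_output standardize each sequence (default TRUE).
#' @return list of `tvi_sequence` objects, or file paths when `out_dir` is
#'   given.
#' @export
surrogate_dataset <- function(n = 64, cfg = surrogate_config(), seed = NULL,
                              out_dir = NULL, preprocess = TRUE,
                              pp_cfg = NULL, standardize_output = TRUE) {
  if (is.null(pp_cfg))
    pp_cfg <- preprocess_config(
      target_shape = c(cfg$grid, round(cfg$duration_s * cfg$sample_rate_hz)),
      target_rate_hz = cfg$sample_rate_hz)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    si <- derive_seed(seed, i)
    s <- generate_surrogate(cfg, seed = si)
    if (preprocess) s <- preprocess_experimental(s, pp_cfg)
    if (standardize_output) s <- standardize(s)
    if (is.null(out_dir)) {
      out[[i]] <- s
    } else {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      p <- file.path(out_dir, sprintf("sur_%03d.h5", i))
      save_tvi(s, p, overwrite = TRUE)
      out[[i]] <- p
    }
  }
  if (!is.null(out_dir)) unlist(out) else out
}
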