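#' Simulation configuration for the in-silico domain
#'
#' Defaults reproduce the generative conditions of a weak isometric
#' contraction (1-5% MVC): 4-10 active motor units with circular territories
#' of 2.5-10 mm diameter placed uniformly in a 40x40 mm^2 cross-section,
#' firing at 8-13 Hz with inter-pulse intervals N(1/FR, (0.2/FR)^2) and 10%
#' of each unit's firings synchronized to another unit.
#'
#' @param n_mus_range integer range of active motor units, default c(4, 10).
#' @param duration_s sequence duration in seconds, default 2.
#' @param grid image grid (rows, cols), default c(128, 128).
#' @param fov_mm field of view in mm, default c(40, 40).
#' @param sample_rate_hz frame rate, default 512.
#' @param fr_range_hz firing-rate range in Hz, default c(8, 13).
#' @param diameter_range_mm territory diameter range, default c(2.5, 10).
#' @param contraction_time_s twitch contraction time T, default 0.025.
#' @param amplitude twitch displacement amplitude (arbitrary units; all data
#'   are standardized before training), default 1.
#' @param ipi_cv coefficient of variation of the inter-pulse interval,
#'   default 0.2.
#' @param ipi_floor_s truncation floor for sampled intervals, default 0.010.
#' @param sync_fraction expected fraction of synchronized firings, default 0.10.
#' @param sync_jitter_s sd of jitter applied when re-aligning a synchronized
#'   firing to a partner unit's firing, default 0.002.
#' @param territory_profile "raised_cosine" (default) or "uniform" spatial
#'   weighting of a territory.
#' @param seed optional integer seed recorded in generated sequences.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_mus_range = c(4L, 10L), duration_s = 2,
                       grid = c(128L, 128L), fov_mm = c(40, 40),
                       sample_rate_hz = 512, fr_range_hz = c(8, 13),
                       diameter_range_mm = c(2.5, 10),
                       contraction_time_s = 0.025, amplitude = 1,
                       ipi_cv = 0.2, ipi_floor_s = 0.010,
                       sync_fraction = 0.10, sync_jitter_s = 0.002,
                       territory_profile = c("raised_cosine", "uniform"),
                       seed = NULL) {
  stopifnot(length(n_mus_range) == 2, n_mus_range[1] >= 1,
            n_mus_range[1] <= n_mus_range[2],
            duration_s > 0, all(grid >= 1), all(fov_mm > 0),
            sample_rate_hz > 0, fr_range_hz[1] > 0,
            fr_range_hz[1] <= fr_range_hz[2],
            diameter_range_mm[1] > 0,
            diameter_range_mm[1] <= diameter_range_mm[2],
            contraction_time_s > 0, ipi_cv >= 0, ipi_floor_s > 0,
            sync_fraction >= 0, sync_fraction <= 1, sync_jitter_s >= 0)
  structure(list(n_mus_range = as.integer(n_mus_range),
                 duration_s = duration_s, grid = as.integer(grid),
                 fov_mm = fov_mm, sample_rate_hz = sample_rate_hz,
                 fr_range_hz = fr_range_hz,
                 diameter_range_mm = diameter_range_mm,
                 contraction_time_s = contraction_time_s,
                 amplitude = amplitude, ipi_cv = ipi_cv,
                 ipi_floor_s = ipi_floor_s, sync_fraction = sync_fraction,
                 sync_jitter_s = sync_jitter_s,
                 territory_profile = match.arg(territory_profile),
                 seed = seed),
            class = "sim_config")
}

#' Sample a motor-unit population
#'
#' MU count is uniform on the configured integer range, centers uniform over
#' the whole cross-section, diameters and firing rates uniform on their
#' ranges.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (NULL uses the current RNG stream).
#' @return data.frame of class `mu_population` with columns
#'   `center_depth_mm`, `center_lateral_mm`, `diameter_mm`, `firing_rate_hz`.
#' @export
sample_population <- function(cfg = sim_config(), seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    n <- sample(seq(cfg$n_mus_range[1], cfg$n_mus_range[2]), 1L)
    pop <- data.frame(
      center_depth_mm = runif(n, 0, cfg$fov_mm[1]),
      center_lateral_mm = runif(n, 0, cfg$fov_mm[2]),
      diameter_mm = runif(n, cfg$diameter_range_mm[1], cfg$diameter_range_mm[2]),
      firing_rate_hz = runif(n, cfg$fr_range_hz[1], cfg$fr_range_hz[2]))
    class(pop) <- c("mu_population", "data.frame")
    pop
  })
}

# Draw one unit's firing train: intervals N(1/FR, (cv/FR)^2) truncated at the
# floor, first firing uniform within one mean interval to randomize phase.
sample_firing_times <- function(fr, duration_s, cv, floor_s) {
  mu <- 1 / fr
  t0 <- runif(1, 0, mu)
  # enough intervals to cover the window with margin
  n_guess <- ceiling(duration_s * fr * 2 + 10)
  times <- numeric(0)
  t_cur <- t0
  while (t_cur <= duration_s) {
    times <- c(times, t_cur)
    ipi <- rnorm(1, mu, cv * mu)
    t_cur <- t_cur + max(ipi, floor_s)
  }
  times
}

#' Generate firing patterns for a motor-unit population
#'
#' Per unit, successive inter-pulse intervals are drawn from
#' N(1/FR, (0.2/FR)^2), truncated at a small positive floor. A
#' Bernoulli(`sync_fraction`) subset of each unit's firings is then
#' re-aligned to the nearest firing of one uniformly drawn partner unit
#' (plus N(0, `sync_jitter_s`^2) jitter) and flagged synchronized. With a
#' single unit the synchronization step is skipped.
#'
#' @param units a `mu_population`.
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return object of class `firing_pattern`: a list with one element per unit,
#'   each `list(times, synchronized)`; times strictly increasing in
#'   `[0, duration_s]`.
#' @export
generate_firing_pattern <- function(units, cfg = sim_config(), seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"), nrow(units) >= 1)
  with_seed(seed, {
    n <- nrow(units)
    base <- lapply(seq_len(n), function(i)
      sample_firing_times(units$firing_rate_hz[i], cfg$duration_s,
                          cfg$ipi_cv, cfg$ipi_floor_s))
    pat <- vector("list", n)
    for (i in seq_len(n)) {
      times <- base[[i]]
      sync <- rep(FALSE, length(times))
      if (n > 1 && cfg$sync_fraction > 0 && length(times)) {
        pick <- runif(length(times)) < cfg$sync_fraction
        for (j in which(pick)) {
          partner <- sample(setdiff(seq_len(n), i), 1L)
          pt <- base[[partner]]
          if (!length(pt)) next
          target <- pt[which.min(abs(pt - times[j]))]
          times[j] <- target + rnorm(1, 0, cfg$sync_jitter_s)
          sync[j] <- TRUE
        }
      }
      times <- pmin(pmax(times, 0), cfg$duration_s)
      ord <- order(times)
      times <- times[ord]; sync <- sync[ord]
      # enforce strict monotonicity after re-alignment
      eps <- 1e-9
      for (j in seq_along(times)[-1])
        if (times[j] <= times[j - 1]) times[j] <- times[j - 1] + eps
      pat[[i]] <- list(times = times, synchronized = sync)
    }
    structure(pat, class = "firing_pattern")
  })
}

#' Motor-unit twitch velocity waveform
#'
#' The displacement twitch is the smooth single-peak transient
#' d(t) = A (t/T)^2 exp(2 (1 - t/T)); the velocity waveform is its time
#' derivative: biphasic (contraction then relaxation), zero at t = 0, and
#' integrating to zero (displacement returns to baseline in isometric steady
#' state).
#'
#' @param t numeric time grid in seconds (values < 0 give 0).
#' @param contraction_time_s time-to-peak T of the displacement twitch.
#' @param amplitude peak displacement A (arbitrary units).
#' @return velocity signal, same length as `t`.
#' @export
twitch_waveform <- function(t, contraction_time_s = 0.025, amplitude = 1) {
  if (!is.numeric(contraction_time_s) || contraction_time_s <= 0)
    stop("`contraction_time_s` must be positive")
  T0 <- contraction_time_s
  u <- t / T0
  v <- amplitude * (2 * u / T0) * (1 - u) * exp(2 * (1 - u))
  v[t < 0] <- 0
  v
}

# Superposed twitch train sampled on a uniform time grid.
twitch_train <- function(times, t_grid, contraction_time_s, amplitude) {
  s <- numeric(length(t_grid))
  for (tf in times)
    s <- s + twitch_waveform(t_grid - tf, contraction_time_s, amplitude)
  s
}

# Spatial weight of a circular territory over grid pixels; returns
# list(idx, w) of in-territory linear pixel indices and weights.
territory_weights <- function(center_depth, center_lateral, diameter, cfg) {
  pitch <- cfg$fov_mm / cfg$grid
  d <- (seq_len(cfg$grid[1]) - 0.5) * pitch[1]
  l <- (seq_len(cfg$grid[2]) - 0.5) * pitch[2]
  r <- sqrt(outer((d - center_depth)^2, (l - center_lateral)^2, "+"))
  R <- diameter / 2
  inside <- which(r <= R)
  w <- if (cfg$territory_profile == "raised_cosine")
    0.5 * (1 + cos(pi * r[inside] / R)) else rep(1, length(inside))
  list(idx = inside, w = w)
}

#' Render a simulated TVI sequence from units and firing patterns
#'
#' Each voxel's time course is the sum over motor units covering that pixel
#' of the unit's twitch train, weighted by the territory's spatial profile.
#' Pixels outside all territories are exactly zero.
#'
#' @param units a `mu_population`.
#' @param pattern matching `firing_pattern`.
#' @param cfg a [sim_config()].
#' @return a `tvi_sequence` with `domain_label = "simulated"`.
#' @export
render_sequence <- function(units, pattern, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"), nrow(units) == length(pattern))
  nfr <- round(cfg$duration_s * cfg$sample_rate_hz)
  t_grid <- (seq_len(nfr) - 1) / cfg$sample_rate_hz
  vm <- matrix(0, cfg$grid[1] * cfg$grid[2], nfr)
  for (i in seq_len(nrow(units))) {
    tw <- territory_weights(units$center_depth_mm[i],
                            units$center_lateral_mm[i],
                            units$diameter_mm[i], cfg)
    if (!length(tw$idx)) next
    s <- twitch_train(pattern[[i]]$times, t_grid,
                      cfg$contraction_time_s, cfg$amplitude)
    vm[tw$idx, ] <- vm[tw$idx, ] + outer(tw$w, s)
  }
  tvi_sequence(array(vm, c(cfg$grid, nfr)),
               pixel_pitch_mm = cfg$fov_mm[1] / cfg$grid[1],
               sample_rate_hz = cfg$sample_rate_hz,
               domain_label = "simulated", seed = cfg$seed)
}

#' Normalized 3D Gaussian smoothing kernel
#'
#' @param sigma_px Gaussian sd per axis in pixels/frames (length 3).
#' @param half_size half extent per axis (default `ceiling(3 * sigma_px)`).
#' @return 3D array summing to 1.
#' @export
smoothing_kernel <- function(sigma_px = c(1.5, 1.5, 1.5),
                             half_size = ceiling(3 * sigma_px)) {
  ax <- lapply(1:3, function(i) {
    x <- seq(-half_size[i], half_size[i])
    if (sigma_px[i] <= 0) as.numeric(x == 0) else exp(-x^2 / (2 * sigma_px[i]^2))
  })
  k <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  k / sum(k)
}

#' Simplified point-source rendering
#'
#' Reduces each territory to a single pixel and each twitch to a unit Dirac
#' impulse at the firing frame, adds white Gaussian noise, then smooths with a
#' normalized 3D low-pass kernel.
#'
#' @param cfg a [sim_config()].
#' @param noise_sd standard deviation of the added white noise; the default
#'   `sqrt(0.1)` reads N(0, 0.1) as a variance.
#' @param kernel normalized 3D smoothing kernel (sum 1) or NULL to skip
#'   smoothing.
#' @param seed integer seed.
#' @return a `tvi_sequence` (`domain_label = "simulated"`).
#' @export
simplified_render <- function(cfg = sim_config(), noise_sd = sqrt(0.1),
                              kernel = smoothing_kernel(), seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(kernel)) {
    if (abs(sum(kernel) - 1) > 1e-6)
      stop("`kernel` must be normalized (sum to 1)")
    if (any(dim(kernel) > c(cfg$grid, round(cfg$duration_s * cfg$sample_rate_hz))))
      stop("kernel larger than the grid")
  }
  with_seed(seed, {
    units <- sample_population(cfg)
    pattern <- generate_firing_pattern(units, cfg)
    nfr <- round(cfg$duration_s * cfg$sample_rate_hz)
    pitch <- cfg$fov_mm / cfg$grid
    v <- array(0, c(cfg$grid, nfr))
    for (i in seq_len(nrow(units))) {
      pi_ <- pmin(pmax(ceiling(units$center_depth_mm[i] / pitch[1]), 1), cfg$grid[1])
      pj <- pmin(pmax(ceiling(units$center_lateral_mm[i] / pitch[2]), 1), cfg$grid[2])
      fr <- pmin(pmax(round(pattern[[i]]$times * cfg$sample_rate_hz) + 1, 1), nfr)
      for (f in fr) v[pi_, pj, f] <- v[pi_, pj, f] + 1
    }
    if (noise_sd > 0) v <- v + array(rnorm(length(v), 0, noise_sd), dim(v))
    if (!is.null(kernel)) v <- conv3d_circular_fft(v, kernel)
    tvi_sequence(v, pixel_pitch_mm = pitch[1],
                 sample_rate_hz = cfg$sample_rate_hz,
                 domain_label = "simulated", seed = seed)
  })
}

#' Generate a set of simulated sequences (with ground-truth manifest)
#'
#' @param n number of sequences (defaults follow the study design: 128 for
#'   training, 64 for testing).
#' @param cfg a [sim_config()].
#' @param seed integer seed; sequence i uses a seed derived from it.
#' @param out_dir optional directory; when given, sequences are written as
#'   `sim_%03d.h5` with a JSON manifest of sampled MU parameters and firing
#'   times, and file paths are returned.
#' @param standardize_output standardize each sequence (default TRUE).
#' @return list of `tvi_sequence` objects, or file paths when `out_dir` is
#'   given.
#' @export
simulate_dataset <- function(n = 128, cfg = sim_config(), seed = NULL,
                             out_dir = NULL, standardize_output = TRUE) {
  out <- vector("list", n)
  manifest <- vector("list", n)
  for (i in seq_len(n)) {
    si <- derive_seed(seed, i)
    units <- sample_population(cfg, seed = si)
    pattern <- generate_firing_pattern(units, cfg,
                                       seed = derive_seed(si, 1))
    cfg_i <- cfg; cfg_i$seed <- si
    s <- render_sequence(units, pattern, cfg_i)
    if (standardize_output) s <- standardize(s)
    manifest[[i]] <- list(index = i, seed = si, units = units,
                          firing_times = lapply(pattern, `[[`, "times"))
    if (is.null(out_dir)) {
      out[[i]] <- s
    } else {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      p <- file.path(out_dir, sprintf("sim_%03d.h5", i))
      save_tvi(s, p, overwrite = TRUE)
      out[[i]] <- p
    }
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    return(unlist(out))
  }
  out
}
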