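test_that("population sampling respects the generative ranges", {
  cfg <- sim_config()
  counts <- integer(300)
  dmin <- Inf; dmax <- -Inf; frmin <- Inf; frmax <- -Inf
  for (i in seq_len(300)) {
    pop <- sample_population(cfg, seed = i)
    counts[i] <- nrow(pop)
    dmin <- min(dmin, pop$diameter_mm); dmax <- max(dmax, pop$diameter_mm)
    frmin <- min(frmin, pop$firing_rate_hz); frmax <- max(frmax, pop$firing_rate_hz)
    expect_true(all(pop$center_depth_mm >= 0 & pop$center_depth_mm <= 40))
    expect_true(all(pop$center_lateral_mm >= 0 & pop$center_lateral_mm <= 40))
  }
  expect_true(all(counts >= 4 & counts <= 10))
  expect_setequal(unique(counts), 4:10)   # every count occurs in 300 draws
  expect_gte(dmin, 2.5); expect_lte(dmax, 10)
  expect_gte(frmin, 8); expect_lte(frmax, 13)
  expect_identical(sample_population(cfg, seed = 42),
                   sample_population(cfg, seed = 42))
})

test_that("inter-pulse intervals have the configured mean and CV", {
  cfg <- sim_config(duration_s = 2)
  set.seed(99)
  ipis <- unlist(lapply(seq_len(800), function(i) {
    diff(tvigan:::sample_firing_times(10, 2, cfg$ipi_cv, cfg$ipi_floor_s))
  }))
  expect_gt(length(ipis), 10000)
  expect_equal(mean(ipis), 0.1, tolerance = 0.01)
  expect_equal(sd(ipis) / mean(ipis), 0.2, tolerance = 0.01)
  expect_true(all(ipis >= cfg$ipi_floor_s - 1e-12))
})

test_that("synchronized-firing fraction matches the 10% design", {
  cfg <- sim_config()
  set.seed(5)
  tot <- 0L; syn <- 0L
  for (i in seq_len(120)) {
    pop <- sample_population(cfg)
    pat <- generate_firing_pattern(pop, cfg)
    flags <- unlist(lapply(pat, `[[`, "synchronized"))
    tot <- tot + length(flags); syn <- syn + sum(flags)
  }
  expect_gt(tot, 5000)
  expect_equal(100 * syn / tot, 10, tolerance = 1)
  # firing times strictly increasing and inside the window
  pat <- generate_firing_pattern(sample_population(cfg, seed = 2), cfg, seed = 3)
  for (mu in pat) {
    expect_true(all(diff(mu$times) > 0))
    expect_true(all(mu$times >= 0 & mu$times <= cfg$duration_s))
  }
})

test_that("a single-unit population skips synchronization", {
  cfg <- sim_config(n_mus_range = c(1L, 1L))
  pop <- sample_population(cfg, seed = 1)
  pat <- generate_firing_pattern(pop, cfg, seed = 2)
  expect_false(any(pat[[1]]$synchronized))
})

test_that("expected firing count follows the renewal-process rate", {
  # duration * FR = 2 s * 10 Hz = 20 expected firings
  set.seed(31)
  n <- vapply(seq_len(400), function(i)
    length(tvigan:::sample_firing_times(10, 2, 0.2, 0.01)), 0)
  expect_equal(mean(n), 20, tolerance = 0.5)
})

test_that("twitch waveform is biphasic, zero at onset, linear, integral-free", {
  T0 <- 0.025
  t <- seq(0, 40 * T0, by = 1e-5)
  v <- twitch_waveform(t, T0, amplitude = 2)
  expect_equal(v[1], 0)
  expect_gt(max(v), 0); expect_lt(min(v), 0)         # biphasic
  expect_equal(twitch_waveform(t, T0, 0), rep(0, length(t)))
  expect_equal(twitch_waveform(t, T0, 4), 2 * v)      # linearity
  # displacement returns to baseline: integral ~ 0 (quadrature)
  integral <- sum(v) * 1e-5
  expect_lt(abs(integral), 1e-6 * max(abs(v)) * 40 * T0)
  expect_error(twitch_waveform(t, -1), "positive")
})

test_that("rendering superposes twitch trains inside territories only", {
  cfg <- tiny_sim_cfg(n_mus_range = c(1L, 1L), territory_profile = "raised_cosine")
  pitch0 <- cfg$fov_mm[1] / cfg$grid[1]
  ctr <- (16 - 0.5) * pitch0   # exactly on a pixel center
  units <- data.frame(center_depth_mm = ctr, center_lateral_mm = ctr,
                      diameter_mm = 4, firing_rate_hz = 10)
  class(units) <- c("mu_population", "data.frame")
  pattern <- structure(list(list(times = 0.05, synchronized = FALSE)),
                       class = "firing_pattern")
  s <- render_sequence(units, pattern, cfg)
  expect_identical(s$domain_label, "simulated")
  # pixel at the territory center carries exactly the delayed twitch
  ci <- 16L
  t_grid <- (seq_len(dim(s$velocity)[3]) - 1) / cfg$sample_rate_hz
  expected <- twitch_waveform(t_grid - 0.05, cfg$contraction_time_s,
                              cfg$amplitude)
  expect_equal(s$velocity[ci, ci, ], expected, tolerance = 1e-10)
  # far corner is outside the territory: identically zero
  expect_identical(s$velocity[32, 32, ], rep(0, dim(s$velocity)[3]))
  # zero MUs -> all-zero sequence
  s0 <- render_sequence(units[0, ], structure(list(), class = "firing_pattern"),
                        cfg)
  expect_true(all(s0$velocity == 0))
})

test_that("rendering is linear in the firing pattern", {
  cfg <- tiny_sim_cfg()
  units <- data.frame(center_depth_mm = c(3, 6), center_lateral_mm = c(4, 6),
                      diameter_mm = c(4, 5), firing_rate_hz = c(9, 12))
  class(units) <- c("mu_population", "data.frame")
  p1 <- structure(list(list(times = c(0.03), synchronized = FALSE),
                       list(times = numeric(0), synchronized = logical(0))),
                  class = "firing_pattern")
  p2 <- structure(list(list(times = numeric(0), synchronized = logical(0)),
                       list(times = c(0.10, 0.19), synchronized = c(FALSE, FALSE))),
                  class = "firing_pattern")
  p12 <- structure(list(list(times = c(0.03), synchronized = FALSE),
                        list(times = c(0.10, 0.19), synchronized = c(FALSE, FALSE))),
                   class = "firing_pattern")
  s1 <- render_sequence(units, p1, cfg)
  s2 <- render_sequence(units, p2, cfg)
  s12 <- render_sequence(units, p12, cfg)
  expect_equal(s12$velocity, s1$velocity + s2$velocity, tolerance = 1e-12)
})

test_that("active-pixel spectra concentrate at the firing rate and harmonics", {
  cfg <- sim_config(grid = c(16L, 16L), fov_mm = c(5, 5), duration_s = 2,
                    n_mus_range = c(1L, 1L), diameter_range_mm = c(5, 5))
  set.seed(8)
  units <- sample_population(cfg)
  units$center_depth_mm <- 2.5; units$center_lateral_mm <- 2.5
  pat <- generate_firing_pattern(units, cfg)
  s <- render_sequence(units, pat, cfg)
  px <- s$velocity[8, 8, ]
  ps <- Mod(fft(px - mean(px)))^2
  f <- (seq_along(ps) - 1) * cfg$sample_rate_hz / length(ps)
  half <- f <= cfg$sample_rate_hz / 2
  fpk <- f[half][which.max(ps[half])]
  expect_gte(fpk, 5); expect_lte(fpk, 26)
})

test_that("simplified rendering places impulses, noise and smoothing as configured", {
  cfg <- tiny_sim_cfg(n_mus_range = c(2L, 3L))
  # no noise, no smoothing: only unit impulses at firing frames
  s <- simplified_render(cfg, noise_sd = 0, kernel = NULL, seed = 4)
  v <- s$velocity
  expect_true(all(v %in% 0:3))
  expect_gt(sum(v), 0)
  # noise only: voxel sd recovers noise_sd
  cfg0 <- tiny_sim_cfg(n_mus_range = c(1L, 1L), diameter_range_mm = c(2.5, 2.5))
  s2 <- simplified_render(cfg0, noise_sd = sqrt(0.1), kernel = NULL, seed = 5)
  fired <- s2$velocity != 0  # impulses perturb few voxels; sd over all is fine
  expect_equal(sd(as.vector(s2$velocity)), sqrt(0.1), tolerance = 0.01)
  # smoothing preserves the total mass of an impulse sequence
  k <- smoothing_kernel(c(1, 1, 1))
  s3 <- simplified_render(cfg, noise_sd = 0, kernel = k, seed = 4)
  s3_raw <- simplified_render(cfg, noise_sd = 0, kernel = NULL, seed = 4)
  expect_equal(sum(s3$velocity), sum(s3_raw$velocity), tolerance = 1e-6)
  expect_error(simplified_render(cfg, kernel = k * 2), "normalized")
})

test_that("identical seeds reproduce identical sequences", {
  cfg <- tiny_sim_cfg(seed = 77)
  a <- simulate_dataset(2, cfg, seed = 77)
  b <- simulate_dataset(2, cfg, seed = 77)
  expect_identical(a[[1]]$velocity, b[[1]]$velocity)
  expect_identical(a[[2]]$velocity, b[[2]]$velocity)
})
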