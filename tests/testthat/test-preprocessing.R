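test_that("bandpass preserves in-band tones and removes DC", {
  cfg <- preprocess_config()
  tone <- tone_sequence(20, h = 3, w = 3, t = 1024)
  out <- bandpass_temporal(tone, cfg)
  mid <- 200:824  # avoid filter edge transients
  expect_equal(max(abs(out$velocity[1, 1, mid])),
               max(abs(tone$velocity[1, 1, mid])), tolerance = 0.05)
  dc <- tone_sequence(20, h = 3, w = 3, t = 1024)
  dc$velocity <- dc$velocity + 7
  outdc <- bandpass_temporal(dc, cfg)
  expect_lt(abs(mean(outdc$velocity[2, 2, mid])), 0.05)
  expect_error(bandpass_temporal(tone_sequence(20, t = 256, rate = 90),
                                 preprocess_config()), "Nyquist")
})

test_that("designed bandpass has half-power points at 5 and 50 Hz", {
  cfg <- preprocess_config()
  hp <- bandpass_halfpower_hz(cfg, 512)
  expect_equal(hp[1], 5, tolerance = 0.02 * 5)
  expect_equal(hp[2], 50, tolerance = 0.02 * 50)
  # two-pass stopband suppression >= 40 dB at 0.5 and 200 Hz
  H2 <- bandpass_response(cfg, 512, c(0.5, 200))^2  # |H|^2 = two-pass gain
  expect_true(all(20 * log10(H2) < -40))
})

test_that("bandpass and resampling are linear; median filter is scale-equivariant", {
  set.seed(21)
  cfg <- preprocess_config(target_shape = c(8L, 8L, 64L), target_rate_hz = 256)
  a <- random_sequence(8, 8, 128, seed = 1, rate = 512)
  b <- random_sequence(8, 8, 128, seed = 2, rate = 512)
  lin <- function(f) {
    fa <- f(a)$velocity; fb <- f(b)$velocity
    ab <- a; ab$velocity <- 2 * a$velocity + 3 * b$velocity
    expect_equal(f(ab)$velocity, 2 * fa + 3 * fb, tolerance = 1e-8)
  }
  lin(function(s) bandpass_temporal(s, cfg))
  lin(function(s) resample_sequence(s, cfg))
  m <- median_filter_spatial(a, cfg)
  a4 <- a; a4$velocity <- 4 * a$velocity
  m4 <- median_filter_spatial(a4, cfg)
  expect_equal(m4$velocity, 4 * m$velocity, tolerance = 1e-12)
})

test_that("median filter removes spikes, keeps constants, uses 3x3 at default pitch", {
  expect_identical(tvigan:::median_kernel_px(1, 40 / 128), 3L)
  cfg <- preprocess_config()
  v <- array(5, c(9, 9, 2))
  v[5, 5, 1] <- 100   # isolated spike
  s <- tvi_sequence(v, domain_label = "experimental")
  out <- median_filter_spatial(s, cfg)
  expect_equal(out$velocity[, , 2], matrix(5, 9, 9))   # constant unchanged
  expect_equal(out$velocity[5, 5, 1], 5)               # spike removed
})

test_that("bicubic spatial downsampling matches an analytic Gaussian", {
  # 64x64 smooth Gaussian -> 32x32 should equal the Gaussian sampled at the
  # coarse pixel centers
  g2d <- function(n) {
    x <- (seq_len(n) - 0.5) / n
    exp(-outer((x - 0.5)^2, (x - 0.5)^2, "+") / (2 * 0.15^2))
  }
  v <- array(rep(g2d(64), 2), c(64, 64, 2))
  s <- tvi_sequence(v, pixel_pitch_mm = 40 / 64, sample_rate_hz = 512,
                    domain_label = "experimental")
  cfg <- preprocess_config(target_shape = c(32L, 32L, 2L), target_rate_hz = 512)
  out <- resample_sequence(s, cfg)
  expect_equal(out$velocity[, , 1], g2d(32), tolerance = 0.01)
  expect_equal(out$pixel_pitch_mm, 40 / 32, tolerance = 1e-10)
})

test_that("temporal decimation preserves a 20 Hz tone and updates the rate", {
  tone <- tone_sequence(20, h = 4, w = 4, t = 4096, rate = 2048)
  cfg <- preprocess_config(target_shape = c(4L, 4L, 1024L), target_rate_hz = 512)
  out <- resample_sequence(tone, cfg)
  expect_equal(dim(out$velocity), c(4L, 4L, 1024L))
  expect_equal(out$sample_rate_hz, 512)
  mid <- 200:824
  expect_equal(max(abs(out$velocity[2, 2, mid])), 1, tolerance = 0.02)
})

test_that("identity resampling is exact and upsampling is refused", {
  s <- random_sequence(8, 8, 32)
  cfg <- preprocess_config(target_shape = c(8L, 8L, 32L), target_rate_hz = 512)
  expect_equal(resample_sequence(s, cfg)$velocity, s$velocity, tolerance = 1e-6)
  up <- preprocess_config(target_shape = c(16L, 16L, 32L), target_rate_hz = 512)
  expect_error(resample_sequence(s, up), "downsampling")
})

test_that("the full chain yields the target geometry and is near-idempotent", {
  set.seed(3)
  cfg_s <- surrogate_config(grid = c(32L, 32L), fov_mm = c(10, 10),
                            duration_s = 0.5)
  raw <- generate_surrogate(cfg_s, seed = 9)
  cfg_d <- preprocess_config(target_shape = c(16L, 16L, 128L),
                             target_rate_hz = 256)
  down <- preprocess_experimental(raw, cfg_d)
  expect_equal(dim(down$velocity), c(16L, 16L, 128L))
  expect_equal(down$sample_rate_hz, 256)
  expect_identical(down$domain_label, "surrogate")
  expect_equal(down$pixel_pitch_mm, raw$pixel_pitch_mm * 2, tolerance = 1e-10)
  # a second pass over already-conditioned, strictly in-band content at the
  # target shape changes little (the passband is flat well inside 5-50 Hz)
  set.seed(12)
  tt <- (seq_len(512) - 1) / 512
  xx <- (seq_len(32) - 0.5) / 32
  smooth_map <- function() {
    m <- matrix(0, 32, 32)
    for (k in 1:4)
      m <- m + rnorm(1) * outer(cos(pi * sample(1:3, 1) * xx + runif(1)),
                                cos(pi * sample(1:3, 1) * xx + runif(1)))
    m
  }
  v <- array(0, c(32, 32, 512))
  for (f in c(10, 15, 20, 25, 35))
    v <- v + outer(smooth_map(), sin(2 * pi * f * tt + runif(1) * 2 * pi))
  inband <- tvi_sequence(v, pixel_pitch_mm = 10 / 32, sample_rate_hz = 512,
                         domain_label = "experimental")
  cfg_p <- preprocess_config(target_shape = c(32L, 32L, 512L),
                             target_rate_hz = 512)
  out <- preprocess_experimental(inband, cfg_p)
  out2 <- preprocess_experimental(out, cfg_p)
  mid <- 60:452
  rel <- sqrt(mean((out2$velocity[, , mid] - out$velocity[, , mid])^2)) /
    sqrt(mean(out$velocity[, , mid]^2))
  expect_lt(rel, 0.05)
})
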