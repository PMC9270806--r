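# Small fixtures shared across tests; everything is generated in code.

random_sequence <- function(h = 8, w = 8, t = 16, seed = 1,
                            domain = "simulated", rate = 512,
                            pitch = 40 / 128) {
  set.seed(seed)
  tvi_sequence(array(rnorm(h * w * t), c(h, w, t)),
               pixel_pitch_mm = pitch, sample_rate_hz = rate,
               domain_label = domain, seed = seed)
}

tone_sequence <- function(freq_hz, h = 4, w = 4, t = 1024, rate = 512,
                          amplitude = 1, phase = 0) {
  tt <- (seq_len(t) - 1) / rate
  sig <- amplitude * sin(2 * pi * freq_hz * tt + phase)
  tvi_sequence(array(rep(sig, each = h * w), c(h, w, t)),
               sample_rate_hz = rate, domain_label = "simulated")
}

tiny_sim_cfg <- function(...) {
  args <- modifyList(list(grid = c(32L, 32L), fov_mm = c(10, 10),
                          duration_s = 0.25), list(...))
  do.call(sim_config, args)
}

# Small toy GAN configuration used by architecture/training tests.
toy_gan_cfg <- function(...) {
  gan_config(base_features = 4L, n_resnet_blocks = 1L, ndf = 4L,
             d_layers = 2L, frames_per_crop = 8L, ...)
}
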