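#' Adversarial loss over patch score grids
#'
#' In "lsgan" mode (the training objective):
#' `d_loss = mean((real - 1)^2) + mean(fake^2)` and
#' `g_loss = mean((fake - 1)^2)`. In "logistic" mode the log-likelihood
#' objective is evaluated literally (scores must lie in (0, 1)):
#' `d_loss = -(mean(log real) + mean(log(1 - fake)))`,
#' `g_loss = mean(log(1 - fake))`.
#'
#' @param real_scores,fake_scores discriminator score grids of equal shape.
#' @param mode "lsgan" or "logistic".
#' @return list with `d_loss` and `g_loss`.
#' @export
adversarial_loss <- function(real_scores, fake_scores,
                             mode = c("lsgan", "logistic")) {
  mode <- match.arg(mode)
  if (length(real_scores) == 0 || length(fake_scores) == 0)
    stop("empty score grid")
  if (!identical(dim(real_scores), dim(fake_scores)) &&
      length(real_scores) != length(fake_scores))
    stop("score grids must have the same shape")
  if (mode == "lsgan") {
    list(d_loss = mean((real_scores - 1)^2) + mean(fake_scores^2),
         g_loss = mean((fake_scores - 1)^2))
  } else {
    if (any(real_scores <= 0 | real_scores >= 1) ||
        any(fake_scores <= 0 | fake_scores >= 1))
      stop("logistic mode requires scores in (0, 1)")
    list(d_loss = -(mean(log(real_scores)) + mean(log(1 - fake_scores))),
         g_loss = mean(log(1 - fake_scores)))
  }
}

#' Cycle-consistency loss
#'
#' Mean absolute (L1) difference between an original crop and its cycled
#' reconstruction.
#'
#' @param original,cycled arrays of identical shape.
#' @return nonnegative scalar.
#' @export
cycle_loss <- function(original, cycled) {
  if (!identical(dim(original) %||% length(original),
                 dim(cycled) %||% length(cycled)))
    stop("shape mismatch between original and cycled data")
  mean(abs(cycled - original))
}

#' Identity-mapping regularization loss
#'
#' Penalizes a generator for altering input that is already in its target
#' domain. L1 (mean absolute difference) by default; "l2" uses the mean
#' squared difference.
#'
#' @param domain_sample input already in the generator's target domain.
#' @param generator_output generator output on that same input.
#' @param norm "l1" (default) or "l2".
#' @return nonnegative scalar.
#' @export
identity_loss <- function(domain_sample, generator_output,
                          norm = c("l1", "l2")) {
  norm <- match.arg(norm)
  if (!identical(dim(domain_sample) %||% length(domain_sample),
                 dim(generator_output) %||% length(generator_output)))
    stop("shape mismatch between sample and generator output")
  d <- generator_output - domain_sample
  if (norm == "l1") mean(abs(d)) else mean(d * d)
}

#' Assemble the total cycleGAN loss
#'
#' `L_total = L_GAN_A + L_GAN_B + lambda_a * L_cycle_A + lambda_b * L_cycle_B
#'  + lambda_idt * (L_idt_A + L_idt_B)`.
#'
#' @param gan_a,gan_b adversarial generator losses for each direction.
#' @param cycle_a,cycle_b cycle-consistency losses.
#' @param idt_a,idt_b identity losses (default 0).
#' @param cfg a [gan_config()] supplying the weights.
#' @return a `loss_bundle` list with every component and `L_total`.
#' @export
total_loss <- function(gan_a, gan_b, cycle_a, cycle_b, idt_a = 0, idt_b = 0,
                       cfg = gan_config()) {
  if (cfg$lambda_a < 0 || cfg$lambda_b < 0 || cfg$lambda_idt < 0)
    stop("config error: negative loss weights")
  structure(list(L_GAN_A = gan_a, L_GAN_B = gan_b,
                 L_cycle_A = cycle_a, L_cycle_B = cycle_b,
                 L_idt_A = idt_a, L_idt_B = idt_b,
                 L_total = gan_a + gan_b + cfg$lambda_a * cycle_a +
                   cfg$lambda_b * cycle_b +
                   cfg$lambda_idt * (idt_a + idt_b)),
            class = "loss_bundle")
}
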