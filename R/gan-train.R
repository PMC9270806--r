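# Image buffer of past generated crops used for discriminator updates: with
# probability 0.5 a stored fake is returned (and replaced), otherwise the
# fresh fake passes through.
new_fake_buffer <- function(capacity) {
  env <- new.env(parent = emptyenv())
  env$items <- list()
  env$capacity <- capacity
  env
}

buffer_query <- function(buf, x) {
  if (buf$capacity <= 0L) return(x)
  if (length(buf$items) < buf$capacity) {
    buf$items[[length(buf$items) + 1L]] <- x
    return(x)
  }
  if (runif(1) < 0.5) {
    i <- sample.int(length(buf$items), 1L)
    old <- buf$items[[i]]
    buf$items[[i]] <- x
    old
  } else x
}

as_velocity_array <- function(s) {
  if (inherits(s, "tvi_sequence")) s$velocity
  else if (is.array(s) && length(dim(s)) == 3L) s
  else stop("domain data must be tvi_sequence objects or 3D arrays")
}

#' Train the modified 3D cycleGAN translator
#'
#' Alternating generator/discriminator updates with Adam (beta1 = 0.5) at a
#' constant learning rate. Training sequences are split into non-overlapping
#' `frames_per_crop`-frame crops, sampled randomly with vertical-flip
#' augmentation (probability 0.5). Discriminator updates draw fakes from an
#' image buffer of past generator outputs. Fully deterministic for a fixed
#' `seed` in single precision.
#'
#' @param domain_a,domain_b lists of standardized `tvi_sequence` objects (or
#'   3D arrays) for the simulated and experimental domains.
#' @param cfg a [gan_config()].
#' @param seed integer training seed.
#' @param n_iter optional total iteration override (default:
#'   `epochs * floor(n_crops_A / batch_size)`).
#' @param log_every log interval in iterations (0 disables logging).
#' @return object of class `trained_translator`: generators `G_B` (A to B,
#'   stochastic when configured) and `G_A` (B to A), discriminators, a
#'   per-iteration loss history with epoch labels, and the config snapshot.
#' @export
train_translator <- function(domain_a, domain_b, cfg = gan_config(),
                             seed = NULL, n_iter = NULL, log_every = 50L) {
  if (cfg$adversarial_mode != "lsgan")
    stop("training is implemented for the least-squares (lsgan) objective")
  A <- lapply(domain_a, as_velocity_array)
  B <- lapply(domain_b, as_velocity_array)
  if (!length(A) || !length(B))
    stop("need at least one sequence per domain")
  fpc <- cfg$frames_per_crop
  for (v in c(A, B)) {
    if (dim(v)[3] %% fpc != 0L)
      stop("frames_per_crop (", fpc, ") must divide the sequence length (",
           dim(v)[3], ")")
  }
  crop_pool <- function(seqs) {
    do.call(rbind, lapply(seq_along(seqs), function(i) {
      starts <- seq(1L, dim(seqs[[i]])[3] - fpc + 1L, by = fpc)
      cbind(i, starts)
    }))
  }
  poolA <- crop_pool(A); poolB <- crop_pool(B)
  with_seed(seed, {
    G_B <- build_generator(cfg, stochastic = cfg$noise_injection)
    G_A <- build_generator(cfg, stochastic = FALSE)
    D_A <- build_discriminator(cfg)
    D_B <- build_discriminator(cfg)
    check_generator_shape(G_B, c(dim(A[[1]])[1:2], fpc))
    st <- list(G_A = adam_init(), G_B = adam_init(),
               D_A = adam_init(), D_B = adam_init())
    buf_A <- new_fake_buffer(cfg$buffer_size)
    buf_B <- new_fake_buffer(cfg$buffer_size)
    iters_per_epoch <- max(1L, nrow(poolA) %/% cfg$batch_size)
    total <- if (is.null(n_iter)) cfg$epochs * iters_per_epoch
             else as.integer(n_iter)
    comp_names <- c("G_adv_A", "G_adv_B", "cycle_A", "cycle_B",
                    "idt_A", "idt_B", "G_total", "D_A", "D_B")
    hist <- matrix(NA_real_, total, length(comp_names),
                   dimnames = list(NULL, comp_names))
    draw_crop <- function(pool, seqs) {
      r <- pool[sample.int(nrow(pool), 1L), ]
      v <- seqs[[r[1]]][, , r[2]:(r[2] + fpc - 1L), drop = FALSE]
      if (runif(1) < 0.5) v <- v[rev(seq_len(dim(v)[1])), , , drop = FALSE]
      v
    }
    prec <- cfg$precision_mode
    for (it in seq_len(total)) {
      gGA <- NULL; gGB <- NULL; gDA <- NULL; gDB <- NULL
      acc <- numeric(length(comp_names)); names(acc) <- comp_names
      fakes_A <- vector("list", cfg$batch_size)
      fakes_B <- vector("list", cfg$batch_size)
      reals_A <- vector("list", cfg$batch_size)
      reals_B <- vector("list", cfg$batch_size)
      for (bi in seq_len(cfg$batch_size)) {
        va <- draw_crop(poolA, A); vb <- draw_crop(poolB, B)
        sdim <- dim(va)
        a <- matrix(as.vector(va), 1L); b <- matrix(as.vector(vb), 1L)
        n_vox <- length(a)
        # ---- generator pass -------------------------------------------
        fB <- net_fwd(G_B, a, sdim, precision = prec)
        fA <- net_fwd(G_A, b, sdim, precision = prec)
        recA <- net_fwd(G_A, fB$y, fB$sdim, precision = prec)
        recB <- net_fwd(G_B, fA$y, fA$sdim, precision = prec)
        sFB <- net_fwd(D_B, fB$y, fB$sdim, precision = prec)
        sFA <- net_fwd(D_A, fA$y, fA$sdim, precision = prec)
        adv_B <- mean((sFB$y - 1)^2)   # G_B fools D_B
        adv_A <- mean((sFA$y - 1)^2)
        cyc_A <- mean(abs(recA$y - a))
        cyc_B <- mean(abs(recB$y - b))
        # cycle-A gradient through G_A, then into G_B
        bwd <- net_bwd(G_A, sign(recA$y - a) * (cfg$lambda_a / n_vox),
                       recA$caches)
        gGA <- grads_add(gGA, bwd$grads)
        d_fB <- bwd$dx +
          net_bwd(D_B, 2 * (sFB$y - 1) / length(sFB$y), sFB$caches)$dx
        gGB <- grads_add(gGB, net_bwd(G_B, d_fB, fB$caches)$grads)
        # cycle-B gradient through G_B, then into G_A
        bwd <- net_bwd(G_B, sign(recB$y - b) * (cfg$lambda_b / n_vox),
                       recB$caches)
        gGB <- grads_add(gGB, bwd$grads)
        d_fA <- bwd$dx +
          net_bwd(D_A, 2 * (sFA$y - 1) / length(sFA$y), sFA$caches)$dx
        gGA <- grads_add(gGA, net_bwd(G_A, d_fA, fA$caches)$grads)
        idt_a <- 0; idt_b <- 0
        if (cfg$lambda_idt > 0) {
          iA <- net_fwd(G_A, a, sdim, precision = prec)
          iB <- net_fwd(G_B, b, sdim, precision = prec)
          idt_a <- mean(abs(iA$y - a))
          gGA <- grads_add(gGA, net_bwd(
            G_A, sign(iA$y - a) * (cfg$lambda_idt / n_vox), iA$caches)$grads)
          if (cfg$idt_b_norm == "l1") {
            idt_b <- mean(abs(iB$y - b))
            d_iB <- sign(iB$y - b) * (cfg$lambda_idt / n_vox)
          } else {
            idt_b <- mean((iB$y - b)^2)
            d_iB <- 2 * (iB$y - b) * (cfg$lambda_idt / n_vox)
          }
          gGB <- grads_add(gGB, net_bwd(G_B, d_iB, iB$caches)$grads)
        }
        # ---- discriminator pass (buffered fakes, detached) ------------
        fakes_B[[bi]] <- buffer_query(buf_B, list(y = fB$y, sdim = fB$sdim))
        fakes_A[[bi]] <- buffer_query(buf_A, list(y = fA$y, sdim = fA$sdim))
        reals_A[[bi]] <- list(y = a, sdim = sdim)
        reals_B[[bi]] <- list(y = b, sdim = sdim)
        g_tot <- adv_A + adv_B + cfg$lambda_a * cyc_A + cfg$lambda_b * cyc_B +
          cfg$lambda_idt * (idt_a + idt_b)
        acc <- acc + c(adv_A, adv_B, cyc_A, cyc_B, idt_a, idt_b, g_tot, 0, 0)
      }
      upd <- adam_step(G_A, grads_scale(gGA, 1 / cfg$batch_size), st$G_A,
                       cfg$lr, cfg$beta1)
      G_A <- upd$net; st$G_A <- upd$state
      upd <- adam_step(G_B, grads_scale(gGB, 1 / cfg$batch_size), st$G_B,
                       cfg$lr, cfg$beta1)
      G_B <- upd$net; st$G_B <- upd$state
      d_losses <- c(D_A = 0, D_B = 0)
      for (bi in seq_len(cfg$batch_size)) {
        for (side in c("A", "B")) {
          D <- if (side == "A") D_A else D_B
          real <- if (side == "A") reals_A[[bi]] else reals_B[[bi]]
          fake <- if (side == "A") fakes_A[[bi]] else fakes_B[[bi]]
          sR <- net_fwd(D, real$y, real$sdim, precision = prec)
          sF <- net_fwd(D, fake$y, fake$sdim, precision = prec)
          dl <- 0.5 * (mean((sR$y - 1)^2) + mean(sF$y^2))
          g <- grads_add(
            net_bwd(D, (sR$y - 1) / length(sR$y), sR$caches)$grads,
            net_bwd(D, sF$y / length(sF$y), sF$caches)$grads)
          if (side == "A") gDA <- grads_add(gDA, g) else gDB <- grads_add(gDB, g)
          d_losses[paste0("D_", side)] <-
            d_losses[paste0("D_", side)] + dl
        }
      }
      upd <- adam_step(D_A, grads_scale(gDA, 1 / cfg$batch_size), st$D_A,
                       cfg$lr, cfg$beta1)
      D_A <- upd$net; st$D_A <- upd$state
      upd <- adam_step(D_B, grads_scale(gDB, 1 / cfg$batch_size), st$D_B,
                       cfg$lr, cfg$beta1)
      D_B <- upd$net; st$D_B <- upd$state
      acc <- acc / cfg$batch_size
      acc["D_A"] <- d_losses["D_A"] / cfg$batch_size
      acc["D_B"] <- d_losses["D_B"] / cfg$batch_size
      if (any(!is.finite(acc)))
        stop("numeric failure: non-finite loss component '",
             comp_names[which(!is.finite(acc))[1]], "' at iteration ", it)
      hist[it, ] <- acc
      if (log_every > 0L && it %% log_every == 0L)
        tvi_log(sprintf("iter %d/%d  cycle_A %.4f  cycle_B %.4f  D_A %.4f  D_B %.4f",
                        it, total, acc["cycle_A"], acc["cycle_B"],
                        acc["D_A"], acc["D_B"]))
    }
    history <- as.data.frame(hist)
    history$iter <- seq_len(total)
    history$epoch <- ceiling(history$iter / iters_per_epoch)
    structure(list(generators = list(G_A = G_A, G_B = G_B),
                   discriminators = list(D_A = D_A, D_B = D_B),
                   history = history, config = cfg,
                   iters_per_epoch = iters_per_epoch),
              class = "trained_translator")
  })
}

#' Per-epoch mean of every training loss component
#'
#' @param model a `trained_translator`.
#' @return data.frame with one row per epoch.
#' @export
epoch_history <- function(model) {
  h <- model$history
  agg <- aggregate(h[setdiff(names(h), c("iter", "epoch"))],
                   by = list(epoch = h$epoch), FUN = mean)
  agg
}
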