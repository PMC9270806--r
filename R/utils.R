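#' @useDynLib tvigan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif fft mvfft cor median var sd splinefun nextn
#'   aggregate uniroot setNames
#' @importFrom utils packageVersion modifyList
NULL

.tvigan_env <- new.env(parent = emptyenv())

#' Write a timestamped log line to standard error
#'
#' @param ... message parts, pasted together.
#' @param level log level tag.
#' @export
tvi_log <- function(..., level = "INFO") {
  lvl <- getOption("tvigan.log_level", "INFO")
  ranks <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)
  if (ranks[[level]] < ranks[[lvl]]) return(invisible(NULL))
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ",
                paste0(..., collapse = ""))
  message(msg)
  invisible(NULL)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded stages never disturb
#' the global stream.
#'
#' @param seed integer seed, or NULL to run under the current stream.
#' @param expr expression to evaluate.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Derive a child seed from a parent seed and a stream offset, kept within the
# 32-bit integer range R requires.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483647)
}

#' Round a numeric object to IEEE single precision
#'
#' Used by the mixed-precision mode to emulate float16/float32 storage of
#' activations while keeping normalization statistics in double.
#'
#' @param x numeric vector, matrix or array.
#' @return object of the same shape with values representable in float32.
#' @export
to_float32 <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.vector(x), raw(), size = 4L), "numeric",
               n = length(x), size = 4L)
  dim(y) <- d
  y
}

# Circular (periodic) 3D convolution via FFT with the kernel centred at the
# origin. Periodic extension preserves total mass exactly for a normalized
# kernel.
conv3d_circular_fft <- function(x, kernel) {
  dx <- dim(x); dk <- dim(kernel)
  if (any(dk > dx)) stop("kernel larger than the grid")
  kp <- array(0, dx)
  kp[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kernel
  ctr <- (dk - 1L) %/% 2L
  for (ax in 1:3) {
    if (ctr[ax] > 0) {
      idx <- c((ctr[ax] + 1L):dx[ax], 1L:ctr[ax])
      kp <- switch(ax, kp[idx, , , drop = FALSE], kp[, idx, , drop = FALSE],
                   kp[, , idx, drop = FALSE])
    }
  }
  Re(fft(fft(x) * fft(kp), inverse = TRUE)) / prod(dx)
}

# Per-pixel temporal variance of a h x w x t array, returned as h x w matrix.
pixel_variance <- function(v) {
  d <- dim(v)
  m <- matrix(v, d[1] * d[2], d[3])
  mu <- rowMeans(m)
  vv <- rowSums((m - mu)^2) / (d[3] - 1)
  matrix(vv, d[1], d[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
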