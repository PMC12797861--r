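#' @importFrom stats coef lm sd var median quantile rnorm runif fft
#'   nextn predict smooth.spline t.test p.adjust pt BIC cor complete.cases
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Wrap angles to (-pi, pi]
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# Evaluate an expression with a temporary RNG state; the global stream is
# restored afterwards so generators are pure functions of their seed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(as.numeric(seed) %% 2147483647))
  force(expr)
}

# Splittable integer seed derivation: a small multiply-xor hash of
# (master_seed, index), kept strictly below 2^31 so it is a valid R seed.
# Subject k's stream therefore never depends on how many subjects exist.
derive_seed <- function(master_seed, index) {
  m <- 2147483647 # 2^31 - 1 (prime)
  h <- (as.numeric(master_seed) %% m + 1)
  h <- (h * 48271) %% m
  h <- (h + as.numeric(index) * 69621) %% m
  h <- (h * 16807) %% m
  as.integer(h)
}

# Round half away from zero to `digits` decimals (base round() is half-to-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Analytic signal via FFT (one-sided spectrum doubling).
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Symmetric linear-phase FIR applied with exact group-delay compensation:
# zero phase response in a single FFT convolution pass. `h` must have odd
# length (even order) so the delay (length-1)/2 is integral.
fir_apply <- function(x, h) {
  drop(fir_apply_multi(x, list(h))[, 1])
}

# Same, sharing one forward FFT of `x` across several kernels. Returns a
# length(x) x length(kernels) matrix. Mixed-radix padding keeps the FFTs
# short for arbitrary input lengths.
fir_apply_multi <- function(x, kernels) {
  n <- length(x)
  nh_max <- max(vapply(kernels, length, integer(1)))
  nfft <- nextn(n + nh_max - 1L, c(2, 3, 5))
  xf <- fft(c(x, numeric(nfft - n)))
  out <- matrix(0, n, length(kernels))
  for (j in seq_along(kernels)) {
    h <- kernels[[j]]
    nh <- length(h)
    if (nh %% 2 == 0) abort("FIR kernel must have odd length (even order).")
    delay <- (nh - 1L) / 2L
    y <- Re(fft(xf * fft(c(h, numeric(nfft - nh))), inverse = TRUE)) / nfft
    out[, j] <- y[(delay + 1L):(delay + n)]
  }
  out
}

# Hamming band-pass FIR design; order = `cycles` cycles of the band low edge,
# forced even. Returns the kernel.
design_bandpass <- function(band, srate, cycles = 3) {
  if (band[1] <= 0 || band[2] >= srate / 2 || band[1] >= band[2]) {
    abort("`band` must satisfy 0 < low < high < srate/2.")
  }
  ord <- ceiling(cycles * srate / band[1])
  if (ord %% 2 == 1) ord <- ord + 1
  signal::fir1(ord, c(band[1], band[2]) / (srate / 2), type = "pass")
}

design_bandstop <- function(band, srate, cycles = 3) {
  ord <- ceiling(cycles * srate / band[1])
  if (ord %% 2 == 1) ord <- ord + 1
  signal::fir1(ord, c(band[1], band[2]) / (srate / 2), type = "stop")
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
}
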