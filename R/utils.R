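# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stage label
#'
#' Every stochastic stage of the phantom draws from its own stream so that
#' regenerating one acquisition (say, the LGE volume) never perturbs another.
#' The mix is a Lehmer step modulo 2^31 - 1, keeping the result a valid
#' 32-bit seed.
#'
#' @param seed integer master seed
#' @param salt integer stage offset
#' @return an integer seed in [1, 2^31 - 2]
#' @keywords internal
mix_seed <- function(seed, salt = 0L) {
  m <- 2147483647
  x <- (as.double(seed) %% m) * 48271 + as.double(salt) * 8191 + 1
  as.integer(x %% (m - 1) + 1)
}

# Run `expr` under a given seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Wrap angles (radians) to [0, 2*pi).
wrap_2pi <- function(x) x %% (2 * pi)

# Wrap phase differences to (-pi, pi].
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# Shortest circular distance between two angles in degrees.
ang_dist_deg <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# Circular (periodic) Gaussian smoothing of the columns of a matrix whose
# rows index a uniform angular grid. sigma is in grid bins.
circ_smooth <- function(m, sigma_bins) {
  n <- nrow(m)
  if (sigma_bins <= 0) return(m)
  j <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  k <- exp(-0.5 * (j / sigma_bins)^2)
  k <- k / sum(k)
  fk <- stats::fft(k)
  fm <- stats::mvfft(m * (1 + 0i))
  Re(stats::mvfft(fm * fk, inverse = TRUE)) / n
}

# Sample standard deviation, NA-tolerant.
sd_na <- function(x) stats::sd(x[!is.na(x)])

# Trapezoidal cumulative integral on a uniform grid with spacing h.
cumtrapz_u <- function(y, h) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) / 2)) * h
}
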