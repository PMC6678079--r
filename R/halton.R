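#' Halton sequence (radical-inverse) in a given base
#'
#' Raw van der Corput radical inverse of the integer indices in the given
#' (prime) base: the building block of the quasi-random draws used by the
#' maximum simulated likelihood estimator.
#'
#' @param idx vector of positive integer indices.
#' @param base integer base, `>= 2`.
#' @return numeric vector in (0, 1).
#' @examples
#' halton_sequence(1:4, 2)  # 1/2, 1/4, 3/4, 1/8
#' @export
halton_sequence <- function(idx, base) {
  base <- as.integer(base)
  if (is.na(base) || base < 2L) stop_domain("base must be an integer >= 2")
  i <- as.numeric(idx)
  if (any(i < 1)) stop_domain("indices must be positive")
  h <- numeric(length(i))
  f <- 1 / base
  while (any(i > 0)) {
    h <- h + (i %% base) * f
    i <- i %/% base
    f <- f / base
  }
  h
}

halton_primes <- c(2L, 3L, 5L, 7L, 11L, 13L, 17L, 19L, 23L, 29L, 31L, 37L,
                   41L, 43L, 47L, 53L, 59L, 61L, 67L, 71L, 73L, 79L, 83L,
                   89L, 97L)

#' Quasi-random standard-normal draws for simulated likelihood
#'
#' One Halton dimension (consecutive prime bases) per random coefficient;
#' the first `drop` points of each sequence are discarded, each dimension is
#' random-shift scrambled with uniforms drawn from `seed`, and the result is
#' mapped through the inverse normal CDF.  Crash `i` uses the `R` consecutive
#' points `drop + (i-1)R + 1, ..., drop + iR` of each dimension, so the draw
#' set is fully determined by `(n_crashes, n_random, R, seed)` and is reused
#' across all likelihood evaluations of a fit.
#'
#' @param n_crashes number of crashes.
#' @param n_random total number of random coefficients (both equations).
#' @param R draws per crash, `>= 1`.
#' @param seed integer scramble seed.
#' @param drop leading points discarded from each sequence (default 50).
#' @return An object of class `bivop_draws`: list with the
#'   `n_crashes x n_random x R` array `draws` plus the generating settings.
#' @export
halton_draws <- function(n_crashes, n_random, R, seed, drop = 50L) {
  n_crashes <- as.integer(n_crashes); n_random <- as.integer(n_random)
  R <- as.integer(R)
  if (R < 1L) stop_domain("R must be >= 1")
  if (n_crashes < 1L) stop_domain("n_crashes must be >= 1")
  if (n_random > length(halton_primes))
    stop_domain("too many random coefficients for the prime table")
  arr <- array(numeric(0), dim = c(n_crashes, n_random, R))
  primes <- head(halton_primes, max(n_random, 0L))
  if (n_random > 0L) {
    N <- n_crashes * R
    shifts <- with_seed(seed, runif(n_random))
    for (q in seq_len(n_random)) {
      u <- halton_sequence(drop + seq_len(N), primes[[q]])
      u <- (u + shifts[[q]]) %% 1
      u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
      # point (i-1)*R + r belongs to crash i, draw r
      arr[, q, ] <- matrix(qnorm(u), nrow = n_crashes, ncol = R, byrow = TRUE)
    }
  }
  structure(list(draws = arr, R = R, n_crashes = n_crashes,
                 n_random = n_random, primes = primes,
                 seed = as.integer(seed), drop = as.integer(drop)),
            class = "bivop_draws")
}

#' @export
print.bivop_draws <- function(x, ...) {
  cat("Scrambled Halton draw set:", x$n_crashes, "crashes x", x$n_random,
      "random coefficients x", x$R, "draws (seed", paste0(x$seed, ")\n"))
  invisible(x)
}
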