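# Sobol low-discrepancy sequences (Joe-Kuo direction numbers, dimensions <= 10)
# and their mapping to correlated Gaussian random-effect draws.

# Primitive polynomial degree s, coefficient a, and initial direction numbers
# m for Sobol dimensions 2..10 (dimension 1 is the van der Corput sequence).
.sobol_jk <- list(
  list(s = 1L, a = 0L, m = c(1L)),
  list(s = 2L, a = 1L, m = c(1L, 3L)),
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L)),
  list(s = 4L, a = 4L, m = c(1L, 3L, 5L, 13L)),
  list(s = 5L, a = 2L, m = c(1L, 1L, 5L, 5L, 17L)),
  list(s = 5L, a = 4L, m = c(1L, 1L, 5L, 5L, 5L)),
  list(s = 5L, a = 7L, m = c(1L, 1L, 7L, 11L, 19L))
)

#' Sobol sequence points
#'
#' Generates the first `n` points of the `d`-dimensional Sobol sequence
#' (Gray-code order), optionally with a seeded random digital shift. The
#' first point of the unshifted sequence is the origin; callers integrating
#' through `qnorm()` should drop it (see [qmc_config()]'s `skip`).
#'
#' @param n Number of points.
#' @param d Dimension (1 to 10).
#' @param scramble_seed Integer seed for a random digital-shift scrambling,
#'   or `NULL` (default) for the plain sequence.
#' @return An `n` x `d` matrix with entries in `[0, 1)`.
#' @export
sobol_points <- function(n, d, scramble_seed = NULL) {
  stopifnot(n >= 1, d >= 1)
  if (d > 10) {
    stop("sobol_points() supports at most 10 dimensions", call. = FALSE)
  }
  L <- max(1L, ceiling(log2(n + 1)))
  # direction integers v[k, j], k = 1..L bits
  v <- matrix(0L, nrow = L, ncol = d)
  v[, 1] <- bitwShiftL(1L, L - seq_len(L))
  for (j in seq_len(d)[-1]) {
    pp <- .sobol_jk[[j - 1L]]
    s <- pp$s
    mk <- pp$m
    if (L <= s) {
      v[, j] <- bitwShiftL(mk[seq_len(L)], L - seq_len(L))
    } else {
      vk <- integer(L)
      vk[seq_len(s)] <- bitwShiftL(mk, L - seq_len(s))
      for (k in (s + 1L):L) {
        x <- vk[k - s]
        val <- bitwXor(x, bitwShiftR(x, s))
        if (s > 1L) {
          for (i in seq_len(s - 1L)) {
            if (bitwAnd(bitwShiftR(pp$a, s - 1L - i), 1L) == 1L) {
              val <- bitwXor(val, vk[k - i])
            }
          }
        }
        vk[k] <- val
      }
      v[, j] <- vk
    }
  }
  shift <- integer(d)
  if (!is.null(scramble_seed)) {
    shift <- withr_seed_int(scramble_seed, d, 2^L)
  }
  out <- matrix(0, nrow = n, ncol = d)
  state <- integer(d)
  out[1, ] <- bitwXor(state, shift) / 2^L
  if (n > 1L) {
    for (i in 2:n) {
      c_bit <- lowest_zero_bit(i - 2L) # rightmost zero bit of previous index
      state <- bitwXor(state, v[c_bit, ])
      out[i, ] <- bitwXor(state, shift) / 2^L
    }
  }
  out
}

# index (1-based) of the rightmost zero bit of nonnegative integer i
lowest_zero_bit <- function(i) {
  k <- 1L
  while (bitwAnd(i, 1L) == 1L) {
    i <- bitwShiftR(i, 1L)
    k <- k + 1L
  }
  k
}

# d integers uniform on [0, 2^L) drawn without touching the global RNG stream
withr_seed_int <- function(seed, d, maxv) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  as.integer(floor(stats::runif(d) * maxv))
}

# The same standard-normal draw matrix is reused for every likelihood
# evaluation of a fit (deterministic given the settings); cache it so the
# thousands of finite-difference evaluations do not regenerate it.
.qmc_cache <- new.env(parent = emptyenv())

cached_std_draws <- function(cfg, dim) {
  key <- paste(cfg$S, cfg$skip, dim,
               if (is.null(cfg$scramble_seed)) "plain" else cfg$scramble_seed,
               sep = "_")
  if (is.null(.qmc_cache[[key]])) {
    .qmc_cache[[key]] <- qmc_normal_draws(cfg, dim)
  }
  .qmc_cache[[key]]
}

#' Quasi-Monte-Carlo integration settings
#'
#' @param S Number of Sobol draws used to approximate the random-effect
#'   integral of the marginal likelihood.
#' @param scramble_seed Optional integer; when supplied the Sobol points are
#'   scrambled by a seeded random digital shift, making the draw set
#'   reproducibly randomized. `NULL` uses the plain sequence.
#' @param skip Number of initial Sobol points dropped (default 1: the first
#'   unscrambled point is the origin, whose normal quantile is infinite).
#' @return A list of class `qmc_config`.
#' @export
qmc_config <- function(S = 500, scramble_seed = NULL, skip = 1) {
  stopifnot(S >= 2, skip >= 0)
  structure(list(S = as.integer(S), scramble_seed = scramble_seed,
                 skip = as.integer(skip)),
            class = "qmc_config")
}

#' Gaussian quasi-Monte-Carlo draws for the random effects
#'
#' Maps Sobol points through the inverse standard-normal CDF and scales them
#' by a Cholesky factor, giving `S` deterministic draws from `N(0, L L')`.
#'
#' @param cfg A [qmc_config()].
#' @param dim Dimension of the random-effect vector.
#' @param chol Lower-triangular Cholesky factor `L` (`dim` x `dim`), or
#'   `NULL` for standard-normal draws.
#' @return An `S` x `dim` matrix; bit-identical across calls with equal
#'   arguments.
#' @export
qmc_normal_draws <- function(cfg, dim, chol = NULL) {
  stopifnot(inherits(cfg, "qmc_config"))
  if (cfg$S < 2^dim) {
    warning("QMC draw count S = ", cfg$S, " is small for dimension ", dim)
  }
  u <- sobol_points(cfg$S + cfg$skip, dim, scramble_seed = cfg$scramble_seed)
  if (cfg$skip > 0) u <- u[-seq_len(cfg$skip), , drop = FALSE]
  # guard against an exact 0 (possible under scrambling)
  u[u == 0] <- 0.5 / 2^32
  e <- stats::qnorm(u)
  if (is.null(chol)) e else e %*% t(chol)
}
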