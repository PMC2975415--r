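#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded to `seed`, restoring
#' the caller's RNG state afterwards so seeded helpers never perturb an
#' enclosing simulation.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Shannon entropy (base 2) of a count or probability vector; zero-mass
# categories contribute nothing.
entropy2 <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

clip01 <- function(x) pmax(pmin(x, 1), 0)

# Quasi-uniform unit-sphere directions: Fibonacci lattice of n points.
# `offset` rotates the golden-angle spiral; it is the only seed-dependent
# degree of freedom, so coverage stays uniform for every seed.
fibonacci_sphere <- function(n, offset = 0) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden + offset
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Deterministic angular offset in [0, 2*pi) derived from an integer seed.
seed_offset <- function(seed) {
  (as.numeric(seed) * 0.6180339887498949) %% 1 * 2 * pi
}

`%||%` <- function(a, b) if (is.null(a)) b else a
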