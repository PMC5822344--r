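# Internal helpers: reproducible sub-stream seeding and scoped RNG use.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so seeded package functions do not perturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a named sub-stream seed from a master seed
#'
#' Folds a master seed and any number of integer indices into a single
#' 31-bit seed with a multiplicative congruential mix, so that sweeps and
#' pipeline stages each get an independent, reproducible stream.  Results
#' always lie in \[1, 2^31 - 2\].
#'
#' @param master integer master seed.
#' @param ... integer indices (stage, raft index, replicate, ...).
#' @return A single integer seed.
#' @keywords internal
#' @noRd
spawn_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime (Lehmer modulus)
  s <- as.numeric(master) %% m
  for (k in c(...)) {
    # 69621 * m < 2^53: the product stays exactly representable in a double
    s <- (s * 69621 + as.numeric(k) + 1) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

# argument checks ------------------------------------------------------------

stop_if_not_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

#' 2D rotation matrix
#' @keywords internal
#' @noRd
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}
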