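#' @keywords internal
"_PACKAGE"

# Shared argument checks. Errors name the offending field so that configuration
# mistakes surface at the call site, not deep inside a simulation loop.

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

check_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config(field, "must be a single finite number")
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    stop_config(field, sprintf("must lie in [%g, %g]", lower, upper))
  }
  invisible(x)
}

check_count <- function(x, field, lower = 1L) {
  check_scalar_number(x, field, lower = lower)
  if (x != round(x)) stop_config(field, "must be an integer count")
  invisible(as.integer(x))
}

#' Derive a stream of child seeds from one master seed
#'
#' All randomness in the package is funnelled through one integer seed; child
#' seeds for sub-generators (per trial, per permutation) are derived
#' deterministically so that the same master seed always reproduces the same
#' cohort and the same test statistics. Values stay below 2^31 - 1.
#'
#' @param seed master seed (single integer).
#' @param n number of child seeds.
#' @param stream small integer distinguishing independent consumers.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n, stream = 0L) {
  check_scalar_number(seed, "seed")
  check_count(n, "n")
  # Linear congruential scramble (Numerical Recipes constants) on 2^31-1.
  m <- 2147483647
  x <- (abs(seed) + 1103515245 * (stream + 1)) %% m
  out <- integer(n)
  for (i in seq_len(n)) {
    x <- (1103515245 * ((x + i) %% 65536) + 12345) %% m
    out[i] <- as.integer(x)
  }
  out
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Trapezoidal integral over possibly non-uniform abscissae.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
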