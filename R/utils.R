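#' Wrap angles into (-pi, pi]
#'
#' @param theta numeric vector of angles in radians.
#' @return angles mapped into the half-open interval (-pi, pi].
#' @keywords internal
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  # %% maps -pi to -pi; move it to +pi so the interval is (-pi, pi]
  w[w == -pi] <- pi
  w
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# stopifnot-style check with a formatted message
check_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}

# Run an expression with a locally-seeded RNG, restoring global state after.
# All simulator randomness flows through this single stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler. `kappa = 0` reduces to the circular
#' uniform distribution.
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration parameter, `>= 0`.
#' @return numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  check_that(kappa >= 0, "kappa must be >= 0, got %g", kappa)
  if (kappa < 1e-10) return(wrap_angle(stats::runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  wrap_angle(out + mu)
}
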