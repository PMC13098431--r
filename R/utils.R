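# internal helpers shared across modules

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap angles (degrees) into (-180, 180]; exactly -180 maps to +180 so that
# trans has a single representation
wrap180 <- function(x) {
  out <- ((x + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}

# wrap into [0, 360)
wrap360 <- function(x) x %% 360

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

unitv <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalise a zero-length vector", call. = FALSE)
  a / n
}

# exact truncated-normal sampling by inverse-CDF; vectorised over n.
# bounds may be -Inf/Inf; degenerate windows (both tail probabilities equal)
# fall back to the nearer bound.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (any(lower >= upper)) stop("truncation bounds must satisfy lower < upper",
                                call. = FALSE)
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  x <- stats::qnorm(u, mean, sd)
  # numeric safety at extreme truncation
  pmin(pmax(x, lower), upper)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
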