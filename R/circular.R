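# Circular statistics of dihedral series: wrapped-histogram modes, circular
# mean and resultant length, and a von Mises sampler (Best-Fisher rejection;
# no circular-statistics package is required at run time).

#' Wrapped-histogram mode of a dihedral series
#'
#' Bins the series on a fixed wrapped grid (default 5 degree bins across
#' -180..180) and returns the centre of the most populated bin.  Ties are
#' broken towards the smaller absolute angle, then towards the smaller
#' signed angle, so the result is deterministic.
#'
#' @param degrees dihedral samples in degrees (any real values; wrapped).
#' @param binwidth bin width in degrees (must divide 360; default 5).
#' @return List with `mode` (bin centre, degrees), `half_width`
#'   (`binwidth/2`), `count` (samples in the modal bin), `histogram` (the
#'   [cv_histogram()]).
#' @export
circular_mode <- function(degrees, binwidth = 5) {
  if (length(degrees) < 1L) stop("empty dihedral series", call. = FALSE)
  h <- cv_histogram(degrees, binwidth_x = binwidth, circular_x = TRUE)
  best <- which(h$counts == max(h$counts))
  if (length(best) > 1L) {
    ctr <- h$centers_x[best]
    best <- best[order(abs(ctr), ctr)][1L]
  }
  list(mode = h$centers_x[best], half_width = binwidth / 2,
       count = h$counts[best], histogram = h)
}

#' Circular mean and resultant length
#'
#' Standard directional statistics on wrapped angles: the circular mean is
#' `atan2(mean sin, mean cos)` and the mean resultant length `R` lies in
#' \[0, 1\].  For antipodal or otherwise balanced samples `R` is ~0 and the
#' mean is undefined; it is returned as `NA` with `mean_defined = FALSE`.
#'
#' @param degrees angle samples in degrees.
#' @param tol resultant-length threshold below which the mean is flagged
#'   undefined.
#' @return List with `mean` (degrees in (-180, 180\], `NA` when undefined),
#'   `resultant_length`, `mean_defined`, `n`.
#' @export
circular_stats <- function(degrees, tol = 1e-9) {
  n <- length(degrees)
  if (n < 1L) stop("empty angle series", call. = FALSE)
  rad <- deg2rad(degrees)
  S <- mean(sin(rad)); C <- mean(cos(rad))
  R <- sqrt(S^2 + C^2)
  defined <- R > tol
  list(mean = if (defined) wrap180(rad2deg(atan2(S, C))) else NA_real_,
       resultant_length = R, mean_defined = defined, n = n)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler, vectorised.  Uses R's global random
#' number stream; set a seed upstream for reproducibility.
#'
#' @param n number of samples.
#' @param mu mean direction in degrees.
#' @param kappa concentration (> 0).
#' @return Samples in degrees, wrapped to (-180, 180\].
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa <= 0) stop("kappa must be positive", call. = FALSE)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    m <- ceiling(m * 1.4)  # acceptance rate is high; modest oversampling
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f)))
    out <- c(out, theta[ok])
  }
  wrap180(rad2deg(out[seq_len(n)]) + mu)
}

#' Sample a von Mises mixture of dihedrals
#'
#' Draws `n` dihedral samples from a mixture of von Mises components and
#' records which component generated each sample (ground truth for
#' validation).
#'
#' @param mixture data frame with columns `mean` (degrees), `kappa` (> 0)
#'   and `weight` (summing to 1).
#' @param n number of samples.
#' @param seed optional integer seed (set before sampling when given).
#' @return List with `values` (degrees, (-180, 180\]) and `component`
#'   (integer labels).
#' @export
sample_dihedrals <- function(mixture, n, seed = NULL) {
  stopifnot(is.data.frame(mixture),
            all(c("mean", "kappa", "weight") %in% names(mixture)))
  if (any(mixture$kappa <= 0)) stop("kappa must be positive", call. = FALSE)
  if (abs(sum(mixture$weight) - 1) > 1e-9)
    stop("mixture weights must sum to 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(nrow(mixture), n, replace = TRUE, prob = mixture$weight)
  values <- numeric(n)
  for (k in seq_len(nrow(mixture))) {
    sel <- comp == k
    if (any(sel))
      values[sel] <- rvonmises(sum(sel), mixture$mean[k], mixture$kappa[k])
  }
  list(values = values, component = comp)
}
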