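# Histogram-based free-energy landscapes over one or two collective
# variables, and basin detection.
#
# F_bin = -kB * T * ln(count_bin / count_max), referenced so the most
# populated bin sits at F = 0.  Empty bins are masked, never assigned
# +Inf or a pseudo-count: fabricating barrier heights from unsampled bins is
# worse than admitting a hole in the surface.

KB_KCAL <- 0.0019872041  # kcal mol^-1 K^-1

axis_breaks <- function(x, binwidth, circular) {
  if (binwidth <= 0) stop("binwidth must be positive", call. = FALSE)
  if (circular) {
    if (abs(360 / binwidth - round(360 / binwidth)) > 1e-9)
      stop("circular binwidth must divide 360 degrees", call. = FALSE)
    seq(-180, 180, by = binwidth)
  } else {
    lo <- floor(min(x) / binwidth) * binwidth
    hi <- ceiling(max(x) / binwidth) * binwidth
    # a sample exactly on the top data edge belongs to the upper bin under
    # the half-open rule, so open a bin for it
    if (hi <= max(x)) hi <- hi + binwidth
    if (hi <= lo) hi <- lo + binwidth
    seq(lo, hi, by = binwidth)
  }
}

# wrap circular samples into [-180, 180) so every sample falls in a bin
wrap_for_binning <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w >= 180] <- -180
  w
}

bin_index <- function(x, breaks) {
  # half-open [lo, hi) bins, top edge closed: a sample exactly on an interior
  # edge counts in the upper bin
  findInterval(x, breaks, rightmost.closed = TRUE)
}

#' Histogram over one or two collective variables
#'
#' Bins samples into half-open `[lo, hi)` bins (top edge closed).  Dihedral
#' axes are periodic: declare them with `circular_* = TRUE` to wrap samples
#' at +/-180 degrees onto a fixed -180..180 grid (the binwidth must divide
#' 360).  Non-circular axes get edges aligned to multiples of the binwidth
#' covering the data range.
#'
#' @param x samples for the first collective variable.
#' @param y optional samples for the second collective variable (same
#'   length).
#' @param binwidth_x,binwidth_y bin widths in CV units (defaults: 5 degrees
#'   for dihedral-style axes, 0.25 for distances -- pass explicitly).
#' @param circular_x,circular_y whether the axis wraps at +/-180 degrees.
#' @return An object of class `cv_histogram`: `breaks_x`, `centers_x`,
#'   (`breaks_y`, `centers_y`,) `counts` (vector or matrix), `n`.
#' @export
cv_histogram <- function(x, y = NULL, binwidth_x, binwidth_y = NULL,
                         circular_x = FALSE, circular_y = FALSE) {
  if (length(x) < 1L) stop("empty sample vector", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite samples", call. = FALSE)
  xb <- if (circular_x) wrap_for_binning(x) else x
  breaks_x <- axis_breaks(xb, binwidth_x, circular_x)
  ix <- bin_index(xb, breaks_x)
  nx <- length(breaks_x) - 1L
  if (is.null(y)) {
    counts <- tabulate(ix, nbins = nx)
    out <- list(breaks_x = breaks_x,
                centers_x = breaks_x[-length(breaks_x)] + binwidth_x / 2,
                breaks_y = NULL, centers_y = NULL,
                counts = counts, n = length(x))
  } else {
    if (length(y) != length(x))
      stop("x and y must have equal length", call. = FALSE)
    if (!all(is.finite(y))) stop("non-finite samples", call. = FALSE)
    if (is.null(binwidth_y)) stop("binwidth_y required for 2D histograms",
                                  call. = FALSE)
    yb <- if (circular_y) wrap_for_binning(y) else y
    breaks_y <- axis_breaks(yb, binwidth_y, circular_y)
    iy <- bin_index(yb, breaks_y)
    ny <- length(breaks_y) - 1L
    counts <- matrix(tabulate((iy - 1L) * nx + ix, nbins = nx * ny),
                     nrow = nx, ncol = ny)
    out <- list(breaks_x = breaks_x,
                centers_x = breaks_x[-length(breaks_x)] + binwidth_x / 2,
                breaks_y = breaks_y,
                centers_y = breaks_y[-length(breaks_y)] + binwidth_y / 2,
                counts = counts, n = length(x))
  }
  class(out) <- "cv_histogram"
  out
}

#' Potential of mean force from a histogram
#'
#' Converts bin counts into free energies
#' `F = -kB T ln(count / max(count))` (kcal/mol), referenced to the most
#' populated bin (`min F = 0` over occupied bins).  Empty bins are masked.
#' The default temperature, 333 K, matches a thermophilic simulation
#' protocol; only count ratios enter, so rescaling all counts by a positive
#' constant leaves F unchanged.
#'
#' @param h a [cv_histogram()].
#' @param temperature simulation temperature in kelvin (> 0; default 333).
#' @param unit `"kcal/mol"` (default) or `"kBT"`.
#' @return An object of class `free_energy_surface`: `centers_x`,
#'   (`centers_y`,) `F` (vector/matrix, `NA` where masked), `mask` (TRUE =
#'   empty bin), `counts`, `temperature`, `kBT` (kcal/mol).
#' @export
pmf <- function(h, temperature = 333, unit = c("kcal/mol", "kBT")) {
  stopifnot(inherits(h, "cv_histogram"))
  unit <- match.arg(unit)
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  cmax <- max(h$counts)
  if (cmax == 0L) stop("all histogram bins are empty", call. = FALSE)
  kBT <- KB_KCAL * temperature
  scale <- if (unit == "kcal/mol") kBT else 1
  Fv <- -scale * log(h$counts / cmax)
  mask <- h$counts == 0L
  Fv[mask] <- NA_real_
  structure(list(centers_x = h$centers_x, centers_y = h$centers_y,
                 F = Fv, mask = mask, counts = h$counts,
                 temperature = temperature, kBT = kBT, unit = unit),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  dims <- if (is.matrix(x$F)) paste(dim(x$F), collapse = " x ")
    else length(x$F)
  cat(sprintf(
    "free-energy surface: %s bins, %d masked, T = %g K, max F = %.3f %s\n",
    dims, sum(x$mask), x$temperature, max(x$F, na.rm = TRUE), x$unit))
  invisible(x)
}

#' Local minima (basins) of a free-energy surface
#'
#' Finds unmasked bins whose F does not exceed any unmasked neighbour
#' (8-neighbourhood in 2D, 2-neighbourhood in 1D) and lies at or below
#' `max_F`.  Plateaus of equal F collapse to the lowest-index bin of the
#' plateau, so the result is deterministic.  Basin centres are bin centres;
#' no sub-bin interpolation is attempted.
#'
#' @param s a `free_energy_surface` from [pmf()].
#' @param max_F report only basins with `F <= max_F` (same unit as the
#'   surface; default `Inf`).
#' @return Data frame with columns `x`, (`y`,) `F`, `ix`, (`iy`,) sorted by
#'   ascending F.
#' @export
find_basins <- function(s, max_F = Inf) {
  stopifnot(inherits(s, "free_energy_surface"))
  Fv <- s$F
  if (!is.matrix(Fv)) {
    n <- length(Fv)
    is_min <- logical(n)
    for (i in seq_len(n)) {
      if (is.na(Fv[i])) next
      nb <- Fv[c(i - 1L, i + 1L)[c(i > 1L, i < n)]]
      nb <- nb[!is.na(nb)]
      is_min[i] <- all(Fv[i] <= nb)
    }
    idx <- which(is_min & Fv <= max_F)
    idx <- collapse_plateaus_1d(idx, Fv)
    out <- data.frame(x = s$centers_x[idx], F = Fv[idx], ix = idx)
  } else {
    nx <- nrow(Fv); ny <- ncol(Fv)
    cand <- list()
    for (jx in seq_len(nx)) for (jy in seq_len(ny)) {
      f0 <- Fv[jx, jy]
      if (is.na(f0) || f0 > max_F) next
      ok <- TRUE
      for (dx in -1:1) for (dy in -1:1) {
        if (dx == 0L && dy == 0L) next
        ax <- jx + dx; ay <- jy + dy
        if (ax < 1L || ax > nx || ay < 1L || ay > ny) next
        fn <- Fv[ax, ay]
        if (!is.na(fn) && fn < f0) ok <- FALSE
      }
      if (ok) cand[[length(cand) + 1L]] <- c(jx, jy)
    }
    if (length(cand) == 0L)
      return(data.frame(x = numeric(0), y = numeric(0), F = numeric(0),
                        ix = integer(0), iy = integer(0)))
    cand <- do.call(rbind, cand)
    cand <- collapse_plateaus_2d(cand, Fv)
    out <- data.frame(x = s$centers_x[cand[, 1L]],
                      y = s$centers_y[cand[, 2L]],
                      F = Fv[cand], ix = cand[, 1L], iy = cand[, 2L])
  }
  out[order(out$F, out$ix), , drop = FALSE]
}

# drop all but the first bin of each run of adjacent equal-F minima
collapse_plateaus_1d <- function(idx, Fv) {
  if (length(idx) < 2L) return(idx)
  keep <- rep(TRUE, length(idx))
  for (i in seq_along(idx)[-1L]) {
    if (idx[i] == idx[i - 1L] + 1L && isTRUE(Fv[idx[i]] == Fv[idx[i - 1L]]))
      keep[i] <- FALSE
  }
  idx[keep]
}

# group candidate minima into connected equal-F plateaus (8-connectivity) and
# keep the lowest linear index of each plateau
collapse_plateaus_2d <- function(cand, Fv) {
  nx <- nrow(Fv)
  lin <- (cand[, 2L] - 1L) * nx + cand[, 1L]
  grp <- seq_along(lin)
  repeat {
    changed <- FALSE
    for (i in seq_along(lin)) for (k in seq_along(lin)) {
      if (grp[i] == grp[k]) next
      if (abs(cand[i, 1L] - cand[k, 1L]) <= 1L &&
          abs(cand[i, 2L] - cand[k, 2L]) <= 1L &&
          Fv[cand[i, , drop = FALSE]] == Fv[cand[k, , drop = FALSE]]) {
        g <- min(grp[i], grp[k])
        grp[grp == grp[i] | grp == grp[k]] <- g
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  keep <- vapply(unique(grp), function(g) {
    members <- which(grp == g)
    members[which.min(lin[members])]
  }, integer(1))
  cand[sort(keep), , drop = FALSE]
}
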