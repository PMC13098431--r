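# Cremer-Pople puckering coordinates for six-membered rings, the inverse
# construction, and IUPAC conformer assignment.
#
# Ring atom ordering is fixed to O5, C1, C2, C3, C4, C5 with the phase origin
# at O5 (j = 1).  Under this carbohydrate-community convention the 4C1 chair
# sits at the north pole (theta = 0) and 1C4 at the south pole.  Conformer
# labels are meaningless without the ordering, which is why it is stated here
# and enforced in the documentation of every entry point.

#' Canonical pyranose conformer table
#'
#' The 38 canonical reference conformers of a six-membered ring on the
#' Cremer-Pople sphere: 2 chairs (theta = 0/180), 6 boats and 6 twist-boats
#' alternating every 30 degrees of phi on the equator, and 12 envelopes plus
#' 12 half-chairs alternating every 30 degrees on the theta = 54.74/125.26
#' degree circles (envelopes at phi multiples of 60, half-chairs offset by
#' 30).  The ring oxygen O5 is written `0` in labels (e.g. `0S2`, `1H0`),
#' matching common carbohydrate usage.
#'
#' @return Data frame with columns `name`, `theta`, `phi` (degrees) and
#'   `type` (`C`, `B`, `S`, `E`, `H`).
#' @export
canonical_conformers <- function() {
  th_trop <- rad2deg(acos(1 / sqrt(3)))   # 54.7356...
  north <- c("0E", "0H1", "E1", "2H1", "2E", "2H3",
             "E3", "4H3", "4E", "4H5", "E5", "0H5")
  south <- c("3E", "3H4", "E4", "5H4", "5E", "5H0",
             "E0", "1H0", "1E", "1H2", "E2", "3H2")
  eq <- c("3,0B", "3S1", "B1,4", "5S1", "2,5B", "2S0",
          "B3,0", "1S3", "1,4B", "1S5", "B2,5", "0S2")
  tab <- rbind(
    data.frame(name = "4C1", theta = 0, phi = 0),
    data.frame(name = "1C4", theta = 180, phi = 0),
    data.frame(name = eq, theta = 90, phi = seq(0, 330, by = 30)),
    data.frame(name = north, theta = th_trop, phi = seq(0, 330, by = 30)),
    data.frame(name = south, theta = 180 - th_trop, phi = seq(0, 330, by = 30))
  )
  tab$type <- ifelse(grepl("C", tab$name), "C",
              ifelse(grepl("S", tab$name), "S",
              ifelse(grepl("B", tab$name), "B",
              ifelse(grepl("H", tab$name), "H", "E"))))
  tab
}

#' Cremer-Pople puckering coordinates of a six-membered ring
#'
#' Computes the total puckering amplitude `Q`, the polar angles `theta`
#' (degrees, \[0, 180\]) and `phi` (degrees, \[0, 360)), and the component
#' amplitudes `q2`, `q3` of a ring given in the fixed atom order O5, C1, C2,
#' C3, C4, C5.  The mean plane passes through the geometric centre with its
#' normal taken from the two weighted lattice vectors
#' `R' = sum r_j sin(2 pi (j-1)/6)` and `R'' = sum r_j cos(2 pi (j-1)/6)`;
#' out-of-plane displacements `z_j` then give `q2`, `phi` from the
#' second-order Fourier sums and `q3 = sqrt(1/6) sum (-1)^(j-1) z_j`.
#'
#' An (effectively) planar ring has `Q` below `planarity_tol` and returns
#' `theta`/`phi` as `NA` with `planar = TRUE`; `phi` is numerically unstable
#' as `Q -> 0`.
#'
#' @param frame an `n x 3` coordinate matrix.
#' @param ring 6 distinct atom indices in the order O5, C1, C2, C3, C4, C5.
#' @param planarity_tol amplitude (Angstrom) below which the ring is flagged
#'   planar (default 1e-4 for the raw coordinates; conformer assignment uses
#'   its own 0.1 Angstrom threshold).
#' @return A list of class `pucker_coords`: `Q`, `theta`, `phi`, `q2`, `q3`,
#'   `planar`.
#' @export
cremer_pople <- function(frame, ring, planarity_tol = 1e-4) {
  if (length(ring) != 6L || anyDuplicated(ring))
    stop("ring must give 6 distinct atom indices", call. = FALSE)
  check_frame_index(frame, ring)
  r <- frame[ring, , drop = FALSE]
  ctr <- colMeans(r)
  r <- sweep(r, 2L, ctr)
  j <- 0:5
  ws <- sin(2 * pi * j / 6)
  wc <- cos(2 * pi * j / 6)
  Rp <- colSums(r * ws)
  Rpp <- colSums(r * wc)
  nvec <- vcross(Rp, Rpp)
  if (vnorm(nvec) < 1e-10)
    stop("degenerate ring geometry: mean plane undefined", call. = FALSE)
  z <- as.numeric(r %*% (nvec / vnorm(nvec)))
  c2 <- sqrt(2 / 6) * sum(z * cos(4 * pi * j / 6))
  s2 <- -sqrt(2 / 6) * sum(z * sin(4 * pi * j / 6))
  q2 <- sqrt(c2^2 + s2^2)
  q3 <- sqrt(1 / 6) * sum(z * (-1)^j)
  Q <- sqrt(q2^2 + q3^2)
  if (Q < planarity_tol) {
    out <- list(Q = Q, theta = NA_real_, phi = NA_real_,
                q2 = q2, q3 = q3, planar = TRUE)
  } else {
    theta <- rad2deg(atan2(q2, q3))
    phi <- wrap360(rad2deg(atan2(s2, c2)))
    out <- list(Q = Q, theta = theta, phi = phi, q2 = q2, q3 = q3,
                planar = FALSE)
  }
  class(out) <- "pucker_coords"
  out
}

#' @export
print.pucker_coords <- function(x, ...) {
  if (x$planar) cat(sprintf("pucker: planar (Q = %.4g A)\n", x$Q))
  else cat(sprintf("pucker: Q = %.3f A, theta = %.2f, phi = %.2f\n",
                   x$Q, x$theta, x$phi))
  invisible(x)
}

#' Build a ring from puckering coordinates
#'
#' Inverse Cremer-Pople construction: places six atoms (order O5, C1, C2, C3,
#' C4, C5) on a circle of the given radius with out-of-plane displacements
#' `z_j = sqrt(1/3) q2 cos(phi + 4 pi (j-1)/6) + sqrt(1/6) q3 (-1)^(j-1)`,
#' `q2 = Q sin(theta)`, `q3 = Q cos(theta)`.  `sum z_j = 0` by construction
#' and `cremer_pople()` recovers `(Q, theta, phi)` exactly.
#'
#' @param Q total puckering amplitude in Angstrom (>= 0).
#' @param theta,phi puckering angles in degrees.
#' @param radius in-plane ring radius in Angstrom (default 1.43, a mean
#'   pyranose bond projection; only affects synthetic geometry).
#' @return A `6 x 3` coordinate matrix centred at the origin.
#' @export
build_ring <- function(Q, theta, phi, radius = 1.43) {
  if (Q < 0) stop("Q must be non-negative", call. = FALSE)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  j <- 0:5
  q2 <- Q * sin(deg2rad(theta))
  q3 <- Q * cos(deg2rad(theta))
  z <- sqrt(1 / 3) * q2 * cos(deg2rad(phi) + 4 * pi * j / 6) +
    sqrt(1 / 6) * q3 * (-1)^j
  # clockwise placement viewed from +z so the mean-plane normal recovered by
  # cremer_pople() points along +z
  ang <- 2 * pi * j / 6
  cbind(radius * sin(ang), radius * cos(ang), z)
}

#' Assign the nearest canonical conformer
#'
#' Returns the canonical conformer (from [canonical_conformers()])
#' minimising great-circle distance to `(theta, phi)` on the puckering
#' sphere.  Exact ties are broken lexicographically by name; rings with
#' amplitude below `min_Q` are rejected as planar/unassignable.
#'
#' @param p a `pucker_coords` from [cremer_pople()], or a list with `Q`,
#'   `theta`, `phi`.
#' @param min_Q planarity threshold in Angstrom (default 0.1).
#' @return A list of class `conformer_label`: `name`, `angular_distance`
#'   (degrees), `type`.
#' @export
assign_conformer <- function(p, min_Q = 0.1) {
  if (isTRUE(p$planar) || p$Q < min_Q)
    stop("ring is planar (Q = ", signif(p$Q, 3),
         " A < ", min_Q, "): conformer undefined", call. = FALSE)
  tab <- canonical_conformers()
  d <- great_circle_deg(p$theta, p$phi, tab$theta, tab$phi)
  best <- which(d == min(d))
  if (length(best) > 1L) best <- best[order(tab$name[best])][1L]
  structure(list(name = tab$name[best], angular_distance = d[best],
                 type = tab$type[best]),
            class = "conformer_label")
}

great_circle_deg <- function(th1, ph1, th2, ph2) {
  t1 <- deg2rad(th1); t2 <- deg2rad(th2)
  dp <- deg2rad(ph1 - ph2)
  cosd <- cos(t1) * cos(t2) + sin(t1) * sin(t2) * cos(dp)
  rad2deg(acos(pmin(1, pmax(-1, cosd))))
}

#' @export
print.conformer_label <- function(x, ...) {
  cat(sprintf("conformer %s (%.2f deg from reference)\n",
              x$name, x$angular_distance))
  invisible(x)
}

#' Puckering series and conformer populations over a trajectory
#'
#' Computes Cremer-Pople coordinates for the selected ring in every frame and
#' tabulates conformer populations.  Population fractions are over assigned
#' (non-planar) frames and sum to 1; planar frames are counted separately.
#'
#' @param traj an [md_trajectory()].
#' @param ring an [atom_select()] resolving to exactly 6 atoms in ring order
#'   O5, C1, C2, C3, C4, C5, or a length-6 index vector.
#' @param min_Q planarity threshold passed to [assign_conformer()].
#' @return A list of class `pucker_series`: `frames` (data frame with
#'   `frame`, `Q`, `theta`, `phi`, `conformer`), `populations` (named
#'   fractions over assigned frames), `n_planar`.
#' @export
pucker_series <- function(traj, ring, min_Q = 0.1) {
  stopifnot(inherits(traj, "md_trajectory"))
  idx <- if (inherits(ring, "atom_selection"))
    resolve_selection(traj$topology, ring) else as.integer(ring)
  if (length(idx) != 6L)
    stop("ring selection must resolve to exactly 6 atoms (got ",
         length(idx), ")", call. = FALSE)
  nf <- n_frames(traj)
  Q <- theta <- phi <- numeric(nf)
  conf <- character(nf)
  for (f in seq_len(nf)) {
    p <- cremer_pople(get_frame(traj, f), idx)
    Q[f] <- p$Q
    theta[f] <- p$theta
    phi[f] <- p$phi
    conf[f] <- if (isTRUE(p$planar) || p$Q < min_Q) NA_character_
      else assign_conformer(p, min_Q = min_Q)$name
  }
  assigned <- !is.na(conf)
  pops <- if (any(assigned)) {
    tt <- table(conf[assigned])
    stats::setNames(as.numeric(tt) / sum(tt), names(tt))
  } else stats::setNames(numeric(0), character(0))
  structure(list(
    frames = data.frame(frame = seq_len(nf), Q = Q, theta = theta, phi = phi,
                        conformer = conf, stringsAsFactors = FALSE),
    populations = pops,
    n_planar = sum(!assigned)
  ), class = "pucker_series")
}

#' @export
print.pucker_series <- function(x, ...) {
  cat("pucker_series over", nrow(x$frames), "frames;",
      x$n_planar, "planar/unassigned\n")
  if (length(x$populations)) {
    pp <- sort(x$populations, decreasing = TRUE)
    for (nm in names(pp))
      cat(sprintf("  %-5s %6.2f%%\n", nm, 100 * pp[[nm]]))
  }
  invisible(x)
}
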