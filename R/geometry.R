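# Exact geometric kernels: Euclidean distances, bond/hydride angles, proper
# dihedrals in the IUPAC sign convention, Kabsch least-squares superposition
# (reflection excluded), and per-residue displacement profiles.
#
# No periodic-boundary treatment is applied anywhere: active-site measurements
# are short-range and input frames are assumed to be imaged.

check_frame_index <- function(frame, i) {
  if (any(i < 1L) || any(i > nrow(frame)))
    stop("atom index out of range (frame has ", nrow(frame), " atoms)",
         call. = FALSE)
}

#' Interatomic distance
#'
#' Plain Euclidean distance in Angstrom between two atoms of a frame.
#'
#' @param frame an `n x 3` coordinate matrix (Angstrom).
#' @param i,j distinct atom indices.
#' @return Distance in Angstrom.
#' @export
frame_distance <- function(frame, i, j) {
  check_frame_index(frame, c(i, j))
  if (i == j) stop("distance requires two distinct atoms", call. = FALSE)
  sqrt(sum((frame[i, ] - frame[j, ])^2))
}

#' Bond / three-atom angle
#'
#' Angle at vertex `j` between atoms `i` and `k`, in degrees within
#' \[0, 180\].  A zero-length arm is a degenerate-geometry error.
#'
#' @inheritParams frame_distance
#' @param k third atom index (angle measured at `j`).
#' @return Angle in degrees.
#' @export
frame_angle <- function(frame, i, j, k) {
  check_frame_index(frame, c(i, j, k))
  if (j == i || j == k) stop("angle vertex must differ from the arms",
                             call. = FALSE)
  a <- frame[i, ] - frame[j, ]
  b <- frame[k, ] - frame[j, ]
  na <- vnorm(a); nb <- vnorm(b)
  if (na < 1e-10 || nb < 1e-10)
    stop("degenerate geometry: zero-length angle arm", call. = FALSE)
  cosang <- sum(a * b) / (na * nb)
  rad2deg(acos(pmin(1, pmax(-1, cosang))))
}

#' Proper dihedral angle
#'
#' Torsion of the `i-j-k-l` quartet in degrees, IUPAC sign convention
#' (clockwise positive viewed from `j` towards `k`), range (-180, 180\] with
#' trans mapped to +180.  Collinear `i,j,k` or `j,k,l` make the dihedral
#' undefined and raise an error.
#'
#' @inheritParams frame_angle
#' @param l fourth atom index.
#' @return Dihedral angle in degrees.
#' @export
frame_dihedral <- function(frame, i, j, k, l) {
  check_frame_index(frame, c(i, j, k, l))
  if (j == k) stop("central bond atoms must be distinct", call. = FALSE)
  b1 <- frame[j, ] - frame[i, ]
  b2 <- frame[k, ] - frame[j, ]
  b3 <- frame[l, ] - frame[k, ]
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10)
    stop("undefined dihedral: three consecutive atoms are collinear",
         call. = FALSE)
  b2u <- b2 / vnorm(b2)
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * b2u)
  wrap180(rad2deg(atan2(y, x)))
}

# vectorised per-frame measurements over a trajectory ------------------------

#' Per-frame geometric series over a trajectory
#'
#' Vectorised counterparts of [frame_distance()], [frame_angle()] and
#' [frame_dihedral()] returning one value per frame.
#'
#' @param traj an [md_trajectory()].
#' @param i,j,k,l atom indices.
#' @return Numeric vector of length `n_frames(traj)`.
#' @export
traj_distance <- function(traj, i, j) {
  stopifnot(inherits(traj, "md_trajectory"))
  d <- traj$coords[i, , ] - traj$coords[j, , ]
  if (is.null(dim(d))) d <- matrix(d, nrow = 3L)
  sqrt(colSums(d^2))
}

#' @rdname traj_distance
#' @export
traj_angle <- function(traj, i, j, k) {
  stopifnot(inherits(traj, "md_trajectory"))
  vapply(seq_len(n_frames(traj)),
         function(f) frame_angle(get_frame(traj, f), i, j, k), numeric(1))
}

#' @rdname traj_distance
#' @export
traj_dihedral <- function(traj, i, j, k, l) {
  stopifnot(inherits(traj, "md_trajectory"))
  vapply(seq_len(n_frames(traj)),
         function(f) frame_dihedral(get_frame(traj, f), i, j, k, l),
         numeric(1))
}

#' Kabsch rigid-body superposition
#'
#' Least-squares superposition of `moving` onto `reference` over proper
#' rotations and translations; reflections are excluded by forcing the
#' rotation determinant to +1, so mirror-image point sets retain a positive
#' RMSD.
#'
#' @param moving,reference `n x 3` coordinate matrices with identical `n >= 3`.
#' @return A list of class `superposition` with elements `rotation` (3x3,
#'   det +1), `translation` (length-3), `rmsd` (Angstrom) and `n_atoms`.
#'   The fitted coordinates are `moving %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(moving, reference) {
  moving <- as.matrix(moving); reference <- as.matrix(reference)
  if (!identical(dim(moving), dim(reference)))
    stop("moving and reference must have identical dimensions", call. = FALSE)
  if (ncol(moving) != 3L) stop("coordinates must be n x 3", call. = FALSE)
  n <- nrow(moving)
  if (n < 3L) stop("superposition needs at least 3 atoms", call. = FALSE)
  cm <- colMeans(moving); cr <- colMeans(reference)
  M <- sweep(moving, 2L, cm)
  R <- sweep(reference, 2L, cr)
  H <- t(M) %*% R
  s <- svd(H)
  # collinear (or fully coincident) point sets leave the rotation under-
  # determined: second singular value of the centred cross-covariance vanishes
  sigma <- svd(M, nu = 0, nv = 0)$d
  if (sigma[1L] > 0 && sigma[2L] / sigma[1L] < 1e-10)
    stop("superposition undefined: points are collinear", call. = FALSE)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- M %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - R)^2)))
  structure(list(rotation = rot,
                 translation = as.numeric(cr - rot %*% cm),
                 rmsd = rmsd, n_atoms = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Kabsch superposition: %d atoms, RMSD %.4f A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sp a `superposition` from [kabsch_superpose()].
#' @param coords an `n x 3` matrix.
#' @return Transformed `n x 3` matrix.
#' @export
apply_superposition <- function(sp, coords) {
  stopifnot(inherits(sp, "superposition"))
  sweep(as.matrix(coords) %*% t(sp$rotation), 2L, sp$translation, `+`)
}

as_structure <- function(x, frame = 1L) {
  if (inherits(x, "md_trajectory"))
    return(list(topology = x$topology, coords = get_frame(x, frame)))
  if (is.list(x) && inherits(x$topology, "md_topology") &&
      is.matrix(x$coords))
    return(x)
  stop("expected an md_trajectory or list(topology=, coords=)", call. = FALSE)
}

#' Per-residue displacement profile
#'
#' Superposes structure `b` onto structure `a` using the atoms of
#' `superpose_on` (matched by chain/resid/name), then reports, for every
#' residue covered by `selection`, the mean displacement of its selected
#' atoms.  This is the induced-fit profiling used to quantify loop ordering
#' (e.g. main-chain shifts of a flexible lid upon ligand binding).  Residues
#' present in only one structure are reported with `NA` displacement, never
#' silently as zero.
#'
#' @param a,b structures: [md_trajectory()] objects (first frame used) or
#'   `list(topology=, coords=)`.
#' @param selection an [atom_select()] naming the atoms to profile (e.g. main
#'   chain `name = c("N","CA","C","O")` or `name = "CA"`).
#' @param superpose_on an [atom_select()] defining the fitting region.
#' @return A data frame of class `displacement_profile` with columns `chain`,
#'   `resid`, `resname`, `n_atoms`, `displacement` (Angstrom, `NA` when the
#'   residue is absent from one structure).
#' @export
residue_displacement <- function(a, b, selection, superpose_on) {
  sa <- as_structure(a); sb <- as_structure(b)
  key <- function(top, idx) paste(top$chain[idx], top$resid[idx],
                                  top$name[idx], sep = "/")
  fit_a <- resolve_selection(sa$topology, superpose_on)
  fit_b <- resolve_selection(sb$topology, superpose_on)
  ka <- key(sa$topology, fit_a); kb <- key(sb$topology, fit_b)
  common <- intersect(ka, kb)
  if (length(common) < 3L)
    stop("fewer than 3 common atoms in the superposition region",
         call. = FALSE)
  ia <- fit_a[match(common, ka)]
  ib <- fit_b[match(common, kb)]
  sp <- kabsch_superpose(sb$coords[ib, , drop = FALSE],
                         sa$coords[ia, , drop = FALSE])
  b_fit <- apply_superposition(sp, sb$coords)

  pa <- resolve_selection(sa$topology, selection)
  pb <- resolve_selection(sb$topology, selection)
  kpa <- key(sa$topology, pa); kpb <- key(sb$topology, pb)
  res_key_a <- paste(sa$topology$chain[pa], sa$topology$resid[pa], sep = "/")
  residues <- unique(res_key_a)
  out <- data.frame(chain = character(0), resid = integer(0),
                    resname = character(0), n_atoms = integer(0),
                    displacement = numeric(0), stringsAsFactors = FALSE)
  for (rk in residues) {
    sel_a <- pa[res_key_a == rk]
    k_here <- key(sa$topology, sel_a)
    hit <- match(k_here, kpb)
    chain <- sa$topology$chain[sel_a[1L]]
    resid <- sa$topology$resid[sel_a[1L]]
    resname <- sa$topology$resname[sel_a[1L]]
    if (anyNA(hit)) {
      disp <- NA_real_; nat <- 0L
    } else {
      sel_b <- pb[hit]
      d <- sqrt(rowSums((sa$coords[sel_a, , drop = FALSE] -
                           b_fit[sel_b, , drop = FALSE])^2))
      disp <- mean(d); nat <- length(sel_a)
    }
    out <- rbind(out, data.frame(chain = chain, resid = resid,
                                 resname = resname, n_atoms = nat,
                                 displacement = disp,
                                 stringsAsFactors = FALSE))
  }
  attr(out, "superposition") <- sp
  class(out) <- c("displacement_profile", "data.frame")
  out
}
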