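#' Trajectory container
#'
#' A topology plus an ordered stack of coordinate frames.  Coordinates are in
#' Angstrom and stored as an `n_atoms x 3 x n_frames` array; frames are
#' indexed 1-based in file order.
#'
#' @param topology an [md_topology()].
#' @param coords either an `n_atoms x 3` matrix (single frame), a list of such
#'   matrices, or an `n_atoms x 3 x n_frames` array.
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, coords) {
  stopifnot(inherits(topology, "md_topology"))
  na <- nrow(topology)
  if (is.list(coords) && !is.array(coords)) {
    coords <- array(unlist(coords, use.names = FALSE), dim = c(na, 3L, length(coords)))
  } else if (is.matrix(coords)) {
    coords <- array(coords, dim = c(nrow(coords), 3L, 1L))
  }
  if (length(dim(coords)) != 3L || dim(coords)[2L] != 3L)
    stop("coords must be an n_atoms x 3 x n_frames array", call. = FALSE)
  if (dim(coords)[1L] != na)
    stop("topology mismatch: topology has ", na, " atoms but coordinates have ",
         dim(coords)[1L], call. = FALSE)
  if (dim(coords)[3L] < 1L) stop("trajectory needs at least one frame",
                                 call. = FALSE)
  if (!all(is.finite(coords))) stop("non-finite coordinates in trajectory",
                                    call. = FALSE)
  structure(list(topology = topology, coords = coords),
            class = "md_trajectory")
}

#' @rdname md_trajectory
#' @param x,traj an `md_trajectory`.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "md_trajectory"))
  dim(traj$coords)[3L]
}

#' @rdname md_trajectory
#' @export
n_atoms <- function(traj) {
  stopifnot(inherits(traj, "md_trajectory"))
  dim(traj$coords)[1L]
}

#' @rdname md_trajectory
#' @param i frame index (1-based).
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "md_trajectory"))
  nf <- n_frames(traj)
  if (i < 1L || i > nf) stop("frame index ", i, " out of range 1..", nf,
                             call. = FALSE)
  traj$coords[, , i, drop = TRUE]
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", n_atoms(x), "atoms x", n_frames(x), "frames\n")
  invisible(x)
}
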