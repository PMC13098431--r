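# Structure and trajectory I/O: fixed-column PDB (MODEL/ENDMDL), XYZ
# trajectories, and optional CHARMM/NAMD DCD via bio3d.  All text readers
# accept plain or gzip-compressed input (gzfile() reads both transparently).

read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  # tolerate CRLF and trailing whitespace-only lines
  sub("\r$", "", lines)
}

#' Read an atomic structure
#'
#' Reads a (possibly multi-model, possibly gzipped) PDB file or an XYZ
#' trajectory file into a trajectory object.  For PDB input, one frame is
#' produced per `MODEL` block (a single frame when no `MODEL` records are
#' present); both `ATOM` and `HETATM` records are accepted so that ligands
#' (NAD, CDP, sugars) are retained, and hydrogens are kept when present.
#' Alternate locations: records with altloc `' '` or `'A'` are kept, all
#' others dropped with a single warning.
#'
#' @param path path to the input file (plain or `.gz`).
#' @param format `"pdb"` or `"xyz"`.
#' @return An [md_trajectory()].
#' @export
read_structure <- function(path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  switch(format, pdb = read_pdb_file(path), xyz = read_xyz_file(path))
}

parse_pdb_atom <- function(line, lineno) {
  if (nchar(line) < 54L)
    stop("malformed ATOM/HETATM record at line ", lineno,
         ": record shorter than coordinate fields", call. = FALSE)
  x <- suppressWarnings(as.numeric(substr(line, 31L, 38L)))
  y <- suppressWarnings(as.numeric(substr(line, 39L, 46L)))
  z <- suppressWarnings(as.numeric(substr(line, 47L, 54L)))
  if (anyNA(c(x, y, z)))
    stop("malformed ATOM/HETATM record at line ", lineno,
         ": non-numeric coordinates", call. = FALSE)
  occ <- suppressWarnings(as.numeric(substr(line, 55L, 60L)))
  list(
    serial = suppressWarnings(as.integer(substr(line, 7L, 11L))),
    name = trimws(substr(line, 13L, 16L)),
    altloc = substr(line, 17L, 17L),
    resname = trimws(substr(line, 18L, 21L)),
    chain = substr(line, 22L, 22L),
    resid = suppressWarnings(as.integer(substr(line, 23L, 26L))),
    x = x, y = y, z = z,
    occupancy = if (is.na(occ)) 1 else occ,
    element = trimws(substr(line, 77L, 78L))
  )
}

read_pdb_file <- function(path) {
  lines <- read_text_lines(path)
  rectype <- substr(lines, 1L, 6L)
  is_atom <- rectype %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(lines, "MODEL")
  is_endmdl <- startsWith(lines, "ENDMDL")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path, call. = FALSE)

  # frame id per line: 1 if no MODEL records, else cumulative MODEL count
  if (any(is_model)) {
    frame_of <- cumsum(is_model)
    if (any(is_atom & frame_of == 0L))
      stop("ATOM record before first MODEL in multi-model file ", path,
           call. = FALSE)
  } else {
    frame_of <- rep(1L, length(lines))
  }

  atom_lines <- which(is_atom)
  recs <- lapply(atom_lines, function(i) parse_pdb_atom(lines[i], i))
  altloc <- vapply(recs, `[[`, "", "altloc")
  keep <- altloc %in% c(" ", "", "A")
  if (any(!keep))
    warning(sum(!keep), " atom record(s) with alternate location other than ",
            "' '/'A' dropped", call. = FALSE)
  recs <- recs[keep]
  frames_id <- frame_of[atom_lines][keep]
  if (length(recs) == 0L) stop("no atoms left after altloc filtering",
                               call. = FALSE)

  nf <- max(frames_id)
  first <- which(frames_id == 1L)
  topo <- md_topology(
    serial = vapply(recs[first], `[[`, 0L, "serial"),
    name = vapply(recs[first], `[[`, "", "name"),
    resname = vapply(recs[first], `[[`, "", "resname"),
    resid = vapply(recs[first], `[[`, 0L, "resid"),
    chain = vapply(recs[first], `[[`, "", "chain"),
    element = {
      el <- vapply(recs[first], `[[`, "", "element")
      if (all(nzchar(el))) el else NULL
    },
    altloc = vapply(recs[first], `[[`, "", "altloc"),
    occupancy = vapply(recs[first], `[[`, 0, "occupancy")
  )
  na <- nrow(topo)
  coords <- array(NA_real_, dim = c(na, 3L, nf))
  for (f in seq_len(nf)) {
    idx <- which(frames_id == f)
    if (length(idx) != na)
      stop("MODEL ", f, " has ", length(idx), " atoms; expected ", na,
           call. = FALSE)
    coords[, 1L, f] <- vapply(recs[idx], `[[`, 0, "x")
    coords[, 2L, f] <- vapply(recs[idx], `[[`, 0, "y")
    coords[, 3L, f] <- vapply(recs[idx], `[[`, 0, "z")
  }
  md_trajectory(topo, coords)
}

read_xyz_file <- function(path, topology = NULL) {
  lines <- read_text_lines(path)
  # drop trailing blank lines only
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L) stop("empty XYZ file: ", path, call. = FALSE)
  frames <- list()
  elements <- NULL
  pos <- 1L
  while (pos <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat <= 0L)
      stop("malformed XYZ count line at line ", pos, call. = FALSE)
    if (pos + 1L + nat > length(lines))
      stop("truncated XYZ frame starting at line ", pos, ": expected ", nat,
           " atom lines", call. = FALSE)
    block <- lines[(pos + 2L):(pos + 1L + nat)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    bad <- which(vapply(toks, length, 0L) < 4L)
    if (length(bad))
      stop("malformed XYZ atom line at line ", pos + 1L + bad[1L],
           call. = FALSE)
    el <- vapply(toks, `[[`, "", 1L)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (anyNA(xyz))
      stop("non-numeric coordinates in XYZ frame starting at line ", pos,
           call. = FALSE)
    if (is.null(elements)) elements <- el
    else if (length(el) != length(elements))
      stop("XYZ frame ", length(frames) + 1L, " has ", length(el),
           " atoms; expected ", length(elements), call. = FALSE)
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + nat
  }
  topo <- topology %||% md_topology(
    serial = seq_along(elements), name = make.unique(elements, sep = ""),
    resname = "UNK", resid = 1L, chain = "A", element = elements
  )
  md_trajectory(topo, frames)
}

#' Read a coordinate trajectory against a known topology
#'
#' Frames are returned in file order.  The per-frame atom count must match
#' the topology (a mismatch is a `topology mismatch` error) and a truncated
#' final frame is reported explicitly rather than silently dropped.
#'
#' DCD (CHARMM/NAMD binary) reading is an optional capability backed by the
#' `bio3d` package; see [dcd_supported()].
#'
#' @param topology an [md_topology()].
#' @param path input file path.
#' @param format `"xyz"`, `"pdb"` (multi-model) or `"dcd"`.
#' @return An [md_trajectory()] sharing `topology`.
#' @export
read_trajectory <- function(topology, path, format = c("xyz", "pdb", "dcd")) {
  stopifnot(inherits(topology, "md_topology"))
  format <- match.arg(format)
  if (format == "xyz") {
    traj <- read_xyz_file(path, topology = NULL)
    if (n_atoms(traj) != nrow(topology))
      stop("topology mismatch: file has ", n_atoms(traj),
           " atoms per frame, topology has ", nrow(topology), call. = FALSE)
    return(md_trajectory(topology, traj$coords))
  }
  if (format == "pdb") {
    traj <- read_pdb_file(path)
    if (n_atoms(traj) != nrow(topology))
      stop("topology mismatch: file has ", n_atoms(traj),
           " atoms per frame, topology has ", nrow(topology), call. = FALSE)
    return(md_trajectory(topology, traj$coords))
  }
  # dcd
  if (!dcd_supported())
    stop("DCD support requires the 'bio3d' package", call. = FALSE)
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  nat <- ncol(xyz) / 3L
  if (nat != nrow(topology))
    stop("topology mismatch: DCD has ", nat, " atoms per frame, topology has ",
         nrow(topology), call. = FALSE)
  coords <- array(NA_real_, dim = c(nat, 3L, nrow(xyz)))
  for (f in seq_len(nrow(xyz)))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  md_trajectory(topology, coords)
}

#' @rdname read_trajectory
#' @return `dcd_supported()` returns `TRUE` when the optional DCD reader is
#'   available.
#' @export
dcd_supported <- function() {
  requireNamespace("bio3d", quietly = TRUE)
}

#' Write trajectory frames
#'
#' `write_xyz()` writes an XYZ trajectory (element, x, y, z at 1e-3 Angstrom
#' text precision); `write_pdb()` writes a fixed-column multi-model PDB with
#' `MODEL`/`ENDMDL` blocks.  Both preserve atom order exactly, so
#' write-then-read round trips reproduce coordinates within format precision.
#'
#' @param traj an [md_trajectory()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  top <- traj$topology
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    fr <- traj$coords[, , f, drop = TRUE]
    if (is.null(dim(fr))) fr <- matrix(fr, ncol = 3L)
    writeLines(as.character(nrow(top)), con)
    writeLines(sprintf("frame %d", f), con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f",
                       top$element, fr[, 1L], fr[, 2L], fr[, 3L]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
write_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  top <- traj$topology
  con <- file(path, open = "wt")
  on.exit(close(con))
  # atom name placement per wwPDB: names of <4 chars start in column 14
  aname <- ifelse(nchar(top$name) >= 4L, substr(top$name, 1L, 4L),
                  sprintf(" %-3s", top$name))
  for (f in seq_len(n_frames(traj))) {
    fr <- traj$coords[, , f, drop = TRUE]
    if (is.null(dim(fr))) fr <- matrix(fr, ncol = 3L)
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "HETATM%5d %s %-4s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      top$serial %% 100000L, aname, substr(top$resname, 1L, 4L), top$chain,
      top$resid %% 10000L, fr[, 1L], fr[, 2L], fr[, 3L], top$occupancy, 0,
      top$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
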