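#' Atom topology
#'
#' An ordered table of atom records shared by every frame of a trajectory.
#' Columns: `serial`, `name`, `resname`, `resid`, `chain`, `element`,
#' `altloc`, `occupancy`.  Atom order is significant and identical across all
#' frames; `(chain, resid, name)` must be unique after alternate-location
#' filtering.
#'
#' @param serial integer atom serial numbers.
#' @param name atom names (e.g. `"OH"`, `"NZ"`, `"C4"`); whitespace is
#'   stripped and names must be non-empty.
#' @param resname residue or ligand codes (3-4 characters, e.g. `"TYR"`,
#'   `"NAD"`).
#' @param resid integer residue sequence numbers (author numbering).
#' @param chain one-character chain identifiers.
#' @param element element symbols; guessed from the atom name when missing.
#' @param altloc alternate-location indicators (default `""`).
#' @param occupancy occupancies (default 1).
#'
#' @return A data frame of class `md_topology`.
#' @export
md_topology <- function(serial, name, resname, resid, chain,
                        element = NULL, altloc = "", occupancy = 1) {
  name <- trimws(as.character(name))
  if (length(name) == 0L) stop("topology has zero atoms", call. = FALSE)
  if (any(!nzchar(name))) stop("atom names must be non-empty", call. = FALSE)
  resname <- trimws(as.character(resname))
  chain <- as.character(chain)
  if (is.null(element)) element <- guess_element(name)
  top <- data.frame(
    serial = as.integer(serial),
    name = name,
    resname = resname,
    resid = as.integer(resid),
    chain = chain,
    element = trimws(as.character(element)),
    altloc = as.character(altloc),
    occupancy = as.numeric(occupancy),
    stringsAsFactors = FALSE
  )
  key <- paste(top$chain, top$resid, top$name, sep = "/")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate atom identity after altloc filtering: ", dup,
         call. = FALSE)
  }
  class(top) <- c("md_topology", "data.frame")
  top
}

# crude element guess from a PDB atom name (first alphabetic character,
# honouring two-letter elements only when the name starts in column 13)
guess_element <- function(name) {
  el <- sub("^[0-9']*", "", name)
  substr(el, 1L, 1L)
}

#' @export
print.md_topology <- function(x, ...) {
  cat("md_topology:", nrow(x), "atoms,",
      length(unique(paste(x$chain, x$resid))), "residues\n")
  NextMethod()
}

#' Atom selection
#'
#' A declarative atom selection resolved against a topology.  All supplied
#' fields must match (logical AND); `name` may be a vector of accepted atom
#' names.
#'
#' @param chain,resid,resname,name optional filters; `NULL` means
#'   unconstrained.
#' @return An object of class `atom_selection`.
#' @seealso [resolve_selection()]
#' @export
atom_select <- function(chain = NULL, resid = NULL, resname = NULL,
                        name = NULL) {
  sel <- list(chain = chain, resid = if (!is.null(resid)) as.integer(resid),
              resname = resname, name = name)
  class(sel) <- "atom_selection"
  sel
}

#' @export
format.atom_selection <- function(x, ...) {
  parts <- vapply(names(x), function(f) {
    if (is.null(x[[f]])) NA_character_
    else paste0(f, "=", paste(x[[f]], collapse = "|"))
  }, character(1))
  paste0("[", paste(parts[!is.na(parts)], collapse = ", "), "]")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("atom_selection", format(x), "\n")
  invisible(x)
}

#' Resolve an atom selection to indices
#'
#' Deterministically maps a selection to the strictly increasing atom indices
#' it matches.  An empty resolution is an error that names the unmatched
#' fields, so silent empty selections can never propagate into statistics.
#'
#' @param topology an [md_topology()].
#' @param sel an [atom_select()] object.
#' @return Integer vector of 1-based atom indices, strictly increasing.
#' @export
resolve_selection <- function(topology, sel) {
  stopifnot(inherits(topology, "md_topology"))
  if (!inherits(sel, "atom_selection"))
    stop("`sel` must be an atom_selection", call. = FALSE)
  if (nrow(topology) == 0L) stop("topology is empty", call. = FALSE)
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(sel$chain))   keep <- keep & topology$chain %in% sel$chain
  if (!is.null(sel$resid))   keep <- keep & topology$resid %in% sel$resid
  if (!is.null(sel$resname)) keep <- keep & topology$resname %in% sel$resname
  if (!is.null(sel$name))    keep <- keep & topology$name %in% sel$name
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("empty selection: no atom matches ", format(sel), call. = FALSE)
  idx
}
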