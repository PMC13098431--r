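# Per-frame evaluation of the catalytic-plausibility distance criteria of the
# canonical SDR (short-chain dehydrogenase/reductase) alcohol-oxidation
# geometry, ensemble fractions with Wilson confidence intervals, contact
# sub-censuses and hydride-transfer angle statistics.
#
# A frame is "catalytically plausible" when every heavy-atom distance
# criterion holds at its cutoff (<= semantics: d equal to the cutoff passes).
# The hydride-transfer angle is a reported statistic, not a criterion: the
# plausible fraction is defined by distances alone, with an optional angle
# gate available but off by default.

#' Distance criterion
#'
#' One heavy-atom distance requirement: a probe selection, a target
#' selection, a cutoff in Angstrom and a reduction rule.  With
#' `reduction = "pair"` both selections must resolve to single atoms; with
#' `"min"` the minimum distance over all probe x target pairs is compared to
#' the cutoff (either partner within reach suffices).
#'
#' @param label unique criterion label.
#' @param probe,target [atom_select()] objects (or index vectors).
#' @param cutoff distance cutoff in Angstrom (> 0; default 3.5).
#' @param reduction `"pair"` or `"min"`.
#' @return An object of class `distance_criterion`.
#' @export
distance_criterion <- function(label, probe, target, cutoff = 3.5,
                               reduction = c("pair", "min")) {
  reduction <- match.arg(reduction)
  if (!is.numeric(cutoff) || cutoff <= 0)
    stop("cutoff must be a positive length in Angstrom", call. = FALSE)
  structure(list(label = as.character(label), probe = probe, target = target,
                 cutoff = cutoff, reduction = reduction),
            class = "distance_criterion")
}

#' Criterion set
#'
#' An ordered, conjunctive set of [distance_criterion()]s: a frame is
#' plausible only when all criteria hold.
#'
#' @param name set name (echoed in results).
#' @param criteria list of [distance_criterion()]s with unique labels.
#' @return An object of class `criterion_set`.
#' @export
criterion_set <- function(name, criteria) {
  if (length(criteria) < 1L) stop("need at least one criterion", call. = FALSE)
  if (!all(vapply(criteria, inherits, TRUE, "distance_criterion")))
    stop("criteria must be distance_criterion objects", call. = FALSE)
  labels <- vapply(criteria, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("criterion labels must be unique",
                                  call. = FALSE)
  structure(list(name = name, criteria = criteria, labels = labels),
            class = "criterion_set")
}

#' @export
print.criterion_set <- function(x, ...) {
  cat("criterion_set '", x$name, "' (", length(x$criteria),
      " criteria, all must hold):\n", sep = "")
  for (cr in x$criteria)
    cat(sprintf("  %-22s cutoff %.2f A  (%s)\n", cr$label, cr$cutoff,
                cr$reduction))
  invisible(x)
}

#' Canonical SDR plausibility criteria
#'
#' Builds the four heavy-atom distance criteria of the canonical SDR
#' alcohol-oxidation geometry used to classify frames as catalytically
#' plausible:
#' 1. catalytic-base tyrosine phenolic oxygen within hydrogen-bonding
#'    distance of the reactive sugar C2 oxygen;
#' 2. threonine side-chain oxygen within hydrogen-bonding distance of the
#'    same C2 oxygen;
#' 3. catalytic lysine NZ interacting with the nicotinamide-ribose hydroxyl
#'    oxygens of NAD (minimum over the two oxygens: either within reach
#'    suffices -- the stricter both-oxygens reading can be requested with
#'    `lys_ribose = "both"`, which splits the rule into one criterion per
#'    oxygen);
#' 4. nicotinamide C4 to sugar C2 distance compatible with hydride transfer.
#'
#' All cutoffs default to 3.5 Angstrom and may be overridden; overridden
#' values are echoed in the criterion set.
#'
#' @param bindings named list of [atom_select()] objects providing the roles
#'   `tyr_oh`, `thr_og`, `lys_nz`, `ribose_oh` (one selection matching both
#'   hydroxyl oxygens), `nad_c4`, `sugar_c2`, `sugar_o2`.
#' @param cutoffs named numeric overrides, any of `tyr_oh_o2`, `thr_og_o2`,
#'   `lys_nz_ribose`, `hydride` (Angstrom).
#' @param lys_ribose `"either"` (default, min-over-pairs) or `"both"`.
#' @return A [criterion_set()] of 4 (or 5, with `"both"`) criteria.
#' @export
default_sdr_criteria <- function(bindings, cutoffs = list(),
                                 lys_ribose = c("either", "both")) {
  lys_ribose <- match.arg(lys_ribose)
  roles <- c("tyr_oh", "thr_og", "lys_nz", "ribose_oh", "nad_c4",
             "sugar_c2", "sugar_o2")
  missing <- setdiff(roles, names(bindings))
  if (length(missing))
    stop("binding map is missing role(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  cut <- list(tyr_oh_o2 = 3.5, thr_og_o2 = 3.5, lys_nz_ribose = 3.5,
              hydride = 3.5)
  cut[names(cutoffs)] <- cutoffs
  crits <- list(
    distance_criterion("tyr_oh_o2", bindings$tyr_oh, bindings$sugar_o2,
                       cutoff = cut$tyr_oh_o2, reduction = "pair"),
    distance_criterion("thr_og_o2", bindings$thr_og, bindings$sugar_o2,
                       cutoff = cut$thr_og_o2, reduction = "pair")
  )
  if (lys_ribose == "either") {
    crits <- c(crits, list(
      distance_criterion("lys_nz_ribose", bindings$lys_nz,
                         bindings$ribose_oh, cutoff = cut$lys_nz_ribose,
                         reduction = "min")))
  } else {
    crits <- c(crits, list(
      distance_criterion("lys_nz_ribose_o2", bindings$lys_nz,
                         bindings$ribose_oh_2 %||% bindings$ribose_oh,
                         cutoff = cut$lys_nz_ribose, reduction = "min"),
      distance_criterion("lys_nz_ribose_o3", bindings$lys_nz,
                         bindings$ribose_oh_3 %||% bindings$ribose_oh,
                         cutoff = cut$lys_nz_ribose, reduction = "min")))
  }
  crits <- c(crits, list(
    distance_criterion("hydride", bindings$nad_c4, bindings$sugar_c2,
                       cutoff = cut$hydride, reduction = "pair")))
  criterion_set("canonical SDR alcohol oxidation", crits)
}

resolve_criterion <- function(topology, cr) {
  as_idx <- function(x) {
    if (inherits(x, "atom_selection")) resolve_selection(topology, x)
    else as.integer(x)
  }
  probe <- as_idx(cr$probe)
  target <- as_idx(cr$target)
  if (cr$reduction == "pair" && (length(probe) != 1L || length(target) != 1L))
    stop("criterion '", cr$label, "': reduction 'pair' requires single-atom ",
         "selections (got ", length(probe), " x ", length(target), ")",
         call. = FALSE)
  list(probe = probe, target = target)
}

# minimum probe-target distance per frame, vectorised over frames
criterion_distance_series <- function(traj, probe, target) {
  d <- rep(Inf, n_frames(traj))
  for (p in probe) for (t in target)
    d <- pmin(d, traj_distance(traj, p, t))
  d
}

#' Evaluate the plausibility criteria on a single frame
#'
#' @param frame an `n x 3` coordinate matrix.
#' @param topology the matching [md_topology()].
#' @param cs a [criterion_set()].
#' @return A list of class `frame_verdict`: `distances` (named, Angstrom),
#'   `pass` (named logical; `d <= cutoff` passes, boundary inclusive),
#'   `plausible` (conjunction).
#' @export
evaluate_frame <- function(frame, topology, cs) {
  stopifnot(inherits(cs, "criterion_set"))
  d <- vapply(cs$criteria, function(cr) {
    r <- resolve_criterion(topology, cr)
    min(vapply(r$probe, function(p) min(vapply(r$target, function(t)
      frame_distance(frame, p, t), numeric(1))), numeric(1)))
  }, numeric(1))
  names(d) <- cs$labels
  cutoffs <- vapply(cs$criteria, `[[`, 0, "cutoff")
  pass <- d <= cutoffs
  structure(list(distances = d, pass = pass, plausible = all(pass)),
            class = "frame_verdict")
}

#' Plausibility census over a trajectory
#'
#' Evaluates the criterion set on every frame and reports the plausible
#' fraction with its Wilson 95% confidence interval, per-criterion marginal
#' pass fractions, and the full per-frame verdict table.  Deterministic given
#' its input.
#'
#' @param traj an [md_trajectory()].
#' @param cs a [criterion_set()].
#' @param angle_gate optional list `(c2=, h2=, nad_c4=, min_angle=)` adding a
#'   hydride-angle requirement (degrees) on top of the distance criteria;
#'   `NULL` (default) means distances only.
#' @return A list of class `census_result`: `n_frames`, `n_plausible`,
#'   `fraction`, `ci` (Wilson 95%), `marginals`, `cutoffs`, `verdicts` (data
#'   frame: frame, one distance and pass column per criterion, `plausible`).
#' @export
census <- function(traj, cs, angle_gate = NULL) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(cs, "criterion_set"))
  nf <- n_frames(traj)
  if (nf < 1L) stop("trajectory has no frames", call. = FALSE)
  nc <- length(cs$criteria)
  dmat <- matrix(NA_real_, nrow = nf, ncol = nc,
                 dimnames = list(NULL, cs$labels))
  for (ci in seq_len(nc)) {
    r <- resolve_criterion(traj$topology, cs$criteria[[ci]])
    dmat[, ci] <- criterion_distance_series(traj, r$probe, r$target)
  }
  cutoffs <- vapply(cs$criteria, `[[`, 0, "cutoff")
  pass <- sweep(dmat, 2L, cutoffs, `<=`)
  plausible <- rowSums(pass) == nc
  if (!is.null(angle_gate)) {
    ang <- hydride_angle_series(traj, angle_gate$c2, angle_gate$h2,
                                angle_gate$nad_c4)
    plausible <- plausible & (ang >= angle_gate$min_angle)
  }
  np <- sum(plausible)
  verdicts <- data.frame(frame = seq_len(nf), dmat,
                         pass = pass, plausible = plausible)
  structure(list(
    n_frames = nf, n_plausible = np, fraction = np / nf,
    ci = wilson_ci(np, nf),
    marginals = colMeans(pass),
    cutoffs = stats::setNames(cutoffs, cs$labels),
    criteria = cs, verdicts = verdicts
  ), class = "census_result")
}

# Wilson 95% score interval; prop.test without continuity correction computes
# exactly this interval
wilson_ci <- function(x, n, conf.level = 0.95) {
  ci <- suppressWarnings(
    stats::prop.test(x, n, correct = FALSE, conf.level = conf.level)$conf.int)
  c(lower = ci[1L], upper = ci[2L])
}

#' @export
print.census_result <- function(x, ...) {
  cat(sprintf(
    "census '%s': %d / %d frames plausible (%.3f%%), Wilson 95%% CI [%.3f%%, %.3f%%]\n",
    x$criteria$name, x$n_plausible, x$n_frames, 100 * x$fraction,
    100 * x$ci["lower"], 100 * x$ci["upper"]))
  cat("per-criterion marginal pass fractions:\n")
  for (nm in names(x$marginals))
    cat(sprintf("  %-22s %6.2f%% (cutoff %.2f A)\n", nm,
                100 * x$marginals[[nm]], x$cutoffs[[nm]]))
  invisible(x)
}

#' Contact specification
#'
#' A labelled probe-target contact with its cutoff and denominator
#' convention.  Side-chain amide carbons (Asn CG, Gln CD) are conventionally
#' given a 4.0 Angstrom cutoff because the amide O/N orientation cannot be
#' predefined; backbone carbonyl oxygens use 3.5 Angstrom.
#'
#' @param label contact label.
#' @param probe,target [atom_select()] objects (or index vectors).
#' @param cutoff Angstrom.
#' @param denominator `"all-frames"` or `"plausible-frames"`.
#' @return An object of class `contact_spec`.
#' @export
contact_spec <- function(label, probe, target, cutoff = 3.5,
                         denominator = c("all-frames", "plausible-frames")) {
  denominator <- match.arg(denominator)
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  structure(list(label = label, probe = probe, target = target,
                 cutoff = cutoff, denominator = denominator),
            class = "contact_spec")
}

#' Contact census
#'
#' Fraction of frames in which the minimum probe-target distance is within
#' the contact cutoff.  The denominator is explicit: all frames, or only
#' catalytically plausible frames (which requires per-frame verdicts).  Both
#' denominators are reported when verdicts are supplied, because published
#' contact percentages mix the two conventions and unlabeled fractions are
#' not comparable.  An empty denominator (no plausible frame) is an error,
#' never a silent zero.
#'
#' @param traj an [md_trajectory()].
#' @param contact a [contact_spec()].
#' @param verdicts optional logical vector of per-frame plausibility (e.g.
#'   `census(...)$verdicts$plausible`).
#' @return A list of class `contact_census`: `label`, `cutoff`, `fraction`
#'   (under the spec's denominator), `n`, plus `fraction_all`/`n_all` and,
#'   when verdicts are given, `fraction_plausible`/`n_plausible`.
#' @export
contact_census <- function(traj, contact, verdicts = NULL) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(contact, "contact_spec"))
  r <- resolve_criterion(traj$topology,
                         distance_criterion(contact$label, contact$probe,
                                            contact$target,
                                            cutoff = contact$cutoff,
                                            reduction = "min"))
  hit <- criterion_distance_series(traj, r$probe, r$target) <= contact$cutoff
  out <- list(label = contact$label, cutoff = contact$cutoff,
              fraction_all = mean(hit), n_all = length(hit))
  if (!is.null(verdicts)) {
    if (length(verdicts) != n_frames(traj))
      stop("verdicts length must equal the frame count", call. = FALSE)
    if (!any(verdicts))
      stop("undefined fraction: no plausible frames in the denominator",
           call. = FALSE)
    out$fraction_plausible <- mean(hit[verdicts])
    out$n_plausible <- sum(verdicts)
  }
  if (contact$denominator == "plausible-frames") {
    if (is.null(verdicts))
      stop("denominator 'plausible-frames' requires per-frame verdicts",
           call. = FALSE)
    out$fraction <- out$fraction_plausible
    out$n <- out$n_plausible
  } else {
    out$fraction <- out$fraction_all
    out$n <- out$n_all
  }
  out$denominator <- contact$denominator
  class(out) <- "contact_census"
  out
}

#' @export
print.contact_census <- function(x, ...) {
  cat(sprintf("contact '%s' (cutoff %.1f A): %.3f%% of %s (n = %d)\n",
              x$label, x$cutoff, 100 * x$fraction, x$denominator, x$n))
  invisible(x)
}

hydride_angle_series <- function(traj, c2, h2, nad_c4) {
  as_one <- function(x, role) {
    idx <- if (inherits(x, "atom_selection"))
      resolve_selection(traj$topology, x) else as.integer(x)
    if (length(idx) != 1L)
      stop(role, " must resolve to a single atom", call. = FALSE)
    idx
  }
  i <- as_one(c2, "c2"); j <- as_one(h2, "h2"); k <- as_one(nad_c4, "nad_c4")
  if (!grepl("^H", traj$topology$name[j]) &&
      !identical(toupper(traj$topology$element[j]), "H"))
    stop("missing hydrogen: atom '", traj$topology$name[j],
         "' is not an explicit H2; hydrogens are not reconstructed",
         call. = FALSE)
  traj_angle(traj, i, j, k)
}

#' Hydride-transfer angle statistics
#'
#' Angle at the transferred hydrogen (vertex H2) between the substrate C2 and
#' the nicotinamide C4, per frame, summarised over all frames or a restricted
#' frame set (e.g. the catalytically plausible subset).  Requires an explicit
#' H2 in the topology; no hydrogen positions are inferred.
#'
#' @param traj an [md_trajectory()].
#' @param c2,h2,nad_c4 single-atom [atom_select()]s (or indices).
#' @param restrict_to optional logical per-frame mask.
#' @return List with `mean`, `sd`, `max`, `n`, and the per-frame `series`
#'   (degrees; `NA` outside the restriction).
#' @export
hydride_angle_stats <- function(traj, c2, h2, nad_c4, restrict_to = NULL) {
  ang <- hydride_angle_series(traj, c2, h2, nad_c4)
  keep <- restrict_to %||% rep(TRUE, length(ang))
  if (length(keep) != length(ang))
    stop("restrict_to length must equal the frame count", call. = FALSE)
  sel <- ang[keep]
  if (length(sel) == 0L) stop("restriction leaves no frames", call. = FALSE)
  series <- ang
  series[!keep] <- NA_real_
  list(mean = mean(sel), sd = stats::sd(sel), max = max(sel),
       n = length(sel), series = series)
}
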