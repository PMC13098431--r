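# Synthetic conformational ensembles with planted ground truth.
#
# The generator emits a minimal pseudo-active-site topology and constructs
# per-frame coordinates so that each frame realises its sampled class
# exactly: plausible frames satisfy all four canonical SDR distance criteria
# by truncated sampling below the cutoffs, unproductive frames violate at
# least one designated criterion by truncated sampling above them.  Criterion
# atoms are placed along fixed unit directions from their targets at the
# sampled radial distances, which decouples the criteria so classes can be
# planted as hard guarantees.  This is deliberately non-physical geometry:
# testability outweighs realism, and the statistical structure (fractions,
# distance scales, torsion mixtures, pucker menus) is what the analysis
# stages consume.

#' Synthetic ensemble configuration
#'
#' The generative model for [generate_ensemble()].  Defaults describe a
#' generic sugar-nucleotide/SDR active site: a small plausible fraction,
#' hydrogen-bond-scale distances under the 3.5 Angstrom cutoffs, a
#' single-mode pyrophosphate torsion, a chair-dominated pucker menu and a
#' hydride-transfer angle near 135 degrees.  Use [synthetic_preset()] for
#' the two substrate-mimicking parameterisations.
#'
#' @param n_frames number of frames (> 0).
#' @param fraction_plausible probability that a frame is catalytically
#'   plausible, in \[0, 1\].
#' @param cutoffs the four criterion cutoffs in Angstrom (tyr, thr, lys,
#'   hydride).
#' @param plausible_dist list `(mean, sd, lower)` of the truncated-normal
#'   criterion distances for plausible frames (truncated above at each
#'   cutoff).
#' @param unproductive_dist list `(mean, sd, upper)` for the designated
#'   failing criteria of unproductive frames (truncated below at cutoff).
#' @param failing_criteria indices (1..4) of criteria guaranteed to fail in
#'   unproductive frames.
#' @param passing_dist list `(mean, sd)` for non-designated criteria of
#'   unproductive frames (unconstrained; may pass or fail).
#' @param contacts named list of `(prob, cutoff, target)` contact models for
#'   the probes `asn_cg`, `gln_cd`, `val_o`, `met_o`; `target` is `"O3"` or
#'   `"O4"`.  Contact indicators are Bernoulli, independent of the
#'   plausibility class.
#' @param dihedral_mixture data frame `(mean, kappa, weight)` for the
#'   pyrophosphate O1-P1-O12-P2 torsion.
#' @param pucker_menu data frame `(conformer, prob, noise_sd)`; conformer
#'   names must be canonical ([canonical_conformers()]), probabilities sum
#'   to 1, `noise_sd` is isotropic coordinate noise in Angstrom.
#' @param hydride_angle list `(mean, sd)` in degrees for the C2-H2-C4 angle.
#' @param seed integer seed; identical config + seed gives bitwise-identical
#'   trajectories.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_frames = 1000L,
    fraction_plausible = 0.05,
    cutoffs = c(3.5, 3.5, 3.5, 3.5),
    plausible_dist = list(mean = 3.0, sd = 0.25, lower = 2.5),
    unproductive_dist = list(mean = 4.8, sd = 0.8, upper = 9),
    failing_criteria = c(1L, 4L),
    passing_dist = list(mean = 3.6, sd = 0.5),
    contacts = list(
      asn_cg = list(prob = 0.05, cutoff = 4.0, target = "O3"),
      gln_cd = list(prob = 0.05, cutoff = 4.0, target = "O4"),
      val_o  = list(prob = 0.03, cutoff = 3.5, target = "O3"),
      met_o  = list(prob = 0.01, cutoff = 3.5, target = "O4")),
    dihedral_mixture = data.frame(mean = 170, kappa = 130, weight = 1),
    pucker_menu = data.frame(conformer = "4C1", prob = 1, noise_sd = 0.01,
                             stringsAsFactors = FALSE),
    hydride_angle = list(mean = 135, sd = 8),
    seed = 1L) {
  if (n_frames < 1L) stop("n_frames must be positive", call. = FALSE)
  if (fraction_plausible < 0 || fraction_plausible > 1)
    stop("fraction_plausible must lie in [0, 1]", call. = FALSE)
  if (length(cutoffs) != 4L || any(cutoffs <= 0))
    stop("cutoffs must be 4 positive lengths", call. = FALSE)
  if (!all(failing_criteria %in% 1:4) || length(failing_criteria) < 1L)
    stop("failing_criteria must be a non-empty subset of 1..4", call. = FALSE)
  if (abs(sum(pucker_menu$prob) - 1) > 1e-9)
    stop("pucker menu probabilities must sum to 1", call. = FALSE)
  if (abs(sum(dihedral_mixture$weight) - 1) > 1e-9)
    stop("dihedral mixture weights must sum to 1", call. = FALSE)
  if (any(dihedral_mixture$kappa <= 0))
    stop("dihedral kappa must be positive", call. = FALSE)
  unknown <- setdiff(pucker_menu$conformer, canonical_conformers()$name)
  if (length(unknown))
    stop("unknown conformer name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (plausible_dist$lower >= min(cutoffs))
    stop("infeasible geometry: plausible lower bound reaches the cutoff",
         call. = FALSE)
  cfg <- list(n_frames = as.integer(n_frames),
              fraction_plausible = fraction_plausible,
              cutoffs = cutoffs, plausible_dist = plausible_dist,
              unproductive_dist = unproductive_dist,
              failing_criteria = as.integer(failing_criteria),
              passing_dist = passing_dist, contacts = contacts,
              dihedral_mixture = dihedral_mixture,
              pucker_menu = pucker_menu, hydride_angle = hydride_angle,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Substrate-mimicking presets
#'
#' Two named parameterisations of [synthetic_config()] emulating the
#' statistical structure of glucose- and mannose-side CDP-sugar ensembles:
#' `"cdp-glc-like"` plants a 1.6% plausible fraction, a pyrophosphate
#' torsion mode at 170 degrees and a tightly chair-confined pucker menu;
#' `"cdp-man-like"` plants 4.18%, a mode at 130 degrees and a broader menu
#' with half-chair/envelope/twist-boat excursions.
#'
#' @param name `"cdp-glc-like"` or `"cdp-man-like"`.
#' @param n_frames frames to generate (default 10000).
#' @param seed integer seed.
#' @return A `synthetic_config`.
#' @export
synthetic_preset <- function(name = c("cdp-glc-like", "cdp-man-like"),
                             n_frames = 10000L, seed = 1L) {
  name <- match.arg(name)
  if (name == "cdp-glc-like") {
    synthetic_config(
      n_frames = n_frames, fraction_plausible = 0.016,
      contacts = list(
        asn_cg = list(prob = 0.0018, cutoff = 4.0, target = "O3"),
        gln_cd = list(prob = 0.0100, cutoff = 4.0, target = "O4"),
        val_o  = list(prob = 0.0050, cutoff = 3.5, target = "O3"),
        met_o  = list(prob = 0.0010, cutoff = 3.5, target = "O4")),
      dihedral_mixture = data.frame(mean = 170, kappa = 130, weight = 1),
      pucker_menu = data.frame(
        conformer = c("4C1", "0S2"), prob = c(0.97, 0.03),
        noise_sd = 0.02, stringsAsFactors = FALSE),
      seed = seed)
  } else {
    synthetic_config(
      n_frames = n_frames, fraction_plausible = 0.0418,
      contacts = list(
        asn_cg = list(prob = 0.0020, cutoff = 4.0, target = "O3"),
        gln_cd = list(prob = 0.0033, cutoff = 4.0, target = "O3"),
        val_o  = list(prob = 0.0313, cutoff = 3.5, target = "O3"),
        met_o  = list(prob = 0.0008, cutoff = 3.5, target = "O4")),
      dihedral_mixture = data.frame(mean = 130, kappa = 130, weight = 1),
      pucker_menu = data.frame(
        conformer = c("4C1", "1H0", "1E", "1H2", "0S2"),
        prob = c(0.80, 0.07, 0.05, 0.05, 0.03),
        noise_sd = 0.02, stringsAsFactors = FALSE),
      seed = seed)
  }
}

#' Pseudo-active-site topology of the synthetic ensemble
#'
#' 25 named atoms: the catalytic triad probes (Tyr164 OH, Thr124 OG1, Lys168
#' NZ), the NAD nicotinamide-ribose hydroxyl oxygens (O2R, O3R) and
#' nicotinamide C4, the reactive sugar centre (C2, O2, H2, O3, O4), the four
#' contact probes (Asn125 CG, Gln205 CD, Val83 O, Met85 O), the
#' pyrophosphate quartet (O1, P1, O12, P2) and a separate six-atom pyranose
#' ring (O5, C1..C5).
#'
#' @return An [md_topology()].
#' @export
synthetic_topology <- function() {
  spec <- list(
    c("TYR", 164L, "OH"),  c("THR", 124L, "OG1"), c("LYS", 168L, "NZ"),
    c("NAD", 401L, "O2R"), c("NAD", 401L, "O3R"), c("NAD", 401L, "C4"),
    c("HEX", 501L, "C2"),  c("HEX", 501L, "O2"),  c("HEX", 501L, "H2"),
    c("HEX", 501L, "O3"),  c("HEX", 501L, "O4"),
    c("ASN", 125L, "CG"),  c("GLN", 205L, "CD"),  c("VAL", 83L, "O"),
    c("MET", 85L, "O"),
    c("CDP", 502L, "O1"),  c("CDP", 502L, "P1"),  c("CDP", 502L, "O12"),
    c("CDP", 502L, "P2"),
    c("PYR", 503L, "O5"),  c("PYR", 503L, "C1"),  c("PYR", 503L, "C2"),
    c("PYR", 503L, "C3"),  c("PYR", 503L, "C4"),  c("PYR", 503L, "C5")
  )
  md_topology(
    serial = seq_along(spec),
    name = vapply(spec, `[[`, "", 3L),
    resname = vapply(spec, `[[`, "", 1L),
    resid = as.integer(vapply(spec, `[[`, "", 2L)),
    chain = "A",
    element = substr(vapply(spec, `[[`, "", 3L), 1L, 1L)
  )
}

#' Atom bindings for the synthetic topology
#'
#' The role-to-selection map expected by [default_sdr_criteria()], matching
#' [synthetic_topology()].
#'
#' @return Named list of [atom_select()] objects.
#' @export
synthetic_bindings <- function() {
  list(
    tyr_oh = atom_select(resid = 164, name = "OH"),
    thr_og = atom_select(resid = 124, name = "OG1"),
    lys_nz = atom_select(resid = 168, name = "NZ"),
    ribose_oh = atom_select(resname = "NAD", name = c("O2R", "O3R")),
    nad_c4 = atom_select(resname = "NAD", name = "C4"),
    sugar_c2 = atom_select(resname = "HEX", name = "C2"),
    sugar_o2 = atom_select(resname = "HEX", name = "O2")
  )
}

# fixed placement geometry ----------------------------------------------------
# unit directions from each criterion/contact target to its probe; chosen
# mutually non-parallel so sampled radial distances never interfere
.syn_geom <- list(
  O2 = c(0, 0, 0),
  C2_dir = c(-1, -1, 0) / sqrt(2),     # O2 -> C2, bond length 1.43
  u_tyr = c(1, 0, 0),
  u_thr = c(0, 1, 0),
  NZ = c(4, 4, 4),
  u_rib1 = c(1, 1, -1) / sqrt(3),
  u_rib2 = c(-1, 1, 1) / sqrt(3),
  u_hyd = c(0, 0, 1),                  # C2 -> nicotinamide C4
  O3 = c(1.2, -1.2, 0.5),
  O4 = c(2.2, 0.8, -0.4),
  u_asn = c(0.3, -1, 0.2) / sqrt(1.13),
  u_gln = c(1, 0.5, -0.3) / sqrt(1.34),
  u_val = c(-0.5, 0.2, 1) / sqrt(1.29),
  u_met = c(0, -1, -1) / sqrt(2),
  pp_offset = c(10, 10, 10),
  ring_offset = c(-10, -10, -10)
)

# place the fourth atom of a torsion quartet: bond length b from c, bond
# angle ang (degrees) at c, torsion tau (degrees) about the b->c axis, in the
# sign convention of frame_dihedral()
place_fourth <- function(a, b, c, bond, ang, tau) {
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  ang <- deg2rad(180 - ang)
  tau <- deg2rad(tau)
  d2 <- c(cos(ang), sin(ang) * cos(tau), sin(ang) * sin(tau))
  c + bond * (d2[1L] * bc + d2[2L] * m + d2[3L] * n)
}

# realise a pyrophosphate quartet with the requested O1-P1-O12-P2 torsion
pp_quartet <- function(tau) {
  o1 <- c(1.6 * cos(deg2rad(120)), 1.6 * sin(deg2rad(120)), 0)
  p1 <- c(0, 0, 0)
  o12 <- c(1.6, 0, 0)
  p2 <- place_fourth(o1, p1, o12, 1.6, 120, tau)
  rbind(o1, p1, o12, p2)
}

#' Generate a synthetic ensemble
#'
#' Draws per-frame classes, criterion distances, contact indicators,
#' pyrophosphate torsions, hydride angles and pucker states from the
#' configured distributions, then constructs coordinates realising every
#' sampled value exactly (see the module comments for the placement scheme).
#' Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [synthetic_config()] or [synthetic_preset()].
#' @return List with `trajectory` (an [md_trajectory()] on
#'   [synthetic_topology()]) and `truth`, a data frame with per-frame
#'   `frame`, `plausible`, the four planted criterion distances, one
#'   indicator per contact, `dihedral`, `dihedral_component`, `conformer`,
#'   `hydride_angle`.
#' @export
generate_ensemble <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_frames
  g <- .syn_geom
  top <- synthetic_topology()
  ai <- stats::setNames(seq_len(nrow(top)),
                        paste(top$resname, top$name, sep = "."))

  plaus <- stats::runif(n) < cfg$fraction_plausible

  # criterion distances: plausible truncated below cutoff, designated failing
  # criteria truncated above (strictly, with a 1e-6 margin so the boundary
  # <= semantics cannot flip a planted class)
  eps <- 1e-6
  dmat <- matrix(NA_real_, nrow = n, ncol = 4L)
  for (k in 1:4) {
    cut <- cfg$cutoffs[k]
    dp <- rtruncnorm(n, cfg$plausible_dist$mean, cfg$plausible_dist$sd,
                     lower = cfg$plausible_dist$lower, upper = cut)
    du <- if (k %in% cfg$failing_criteria)
      rtruncnorm(n, cfg$unproductive_dist$mean, cfg$unproductive_dist$sd,
                 lower = cut + eps, upper = cfg$unproductive_dist$upper)
    else
      rtruncnorm(n, cfg$passing_dist$mean, cfg$passing_dist$sd,
                 lower = 1.5, upper = Inf)
    dmat[, k] <- ifelse(plaus, dp, du)
  }

  # contacts: Bernoulli indicator, distance realised on the matching side of
  # the cutoff
  contact_ind <- list()
  contact_d <- list()
  for (nm in names(cfg$contacts)) {
    cc <- cfg$contacts[[nm]]
    ind <- stats::runif(n) < cc$prob
    d_in <- rtruncnorm(n, cc$cutoff - 0.7, 0.3, lower = 2.4,
                       upper = cc$cutoff)
    d_out <- rtruncnorm(n, cc$cutoff + 1.5, 0.8, lower = cc$cutoff + eps,
                        upper = Inf)
    contact_ind[[nm]] <- ind
    contact_d[[nm]] <- ifelse(ind, d_in, d_out)
  }

  dih <- sample_dihedrals(cfg$dihedral_mixture, n)
  hyd <- rtruncnorm(n, cfg$hydride_angle$mean, cfg$hydride_angle$sd,
                    lower = 95, upper = 178)
  conf_id <- sample.int(nrow(cfg$pucker_menu), n, replace = TRUE,
                        prob = cfg$pucker_menu$prob)
  conf_name <- cfg$pucker_menu$conformer[conf_id]
  noise_sd <- cfg$pucker_menu$noise_sd[conf_id]
  ctab <- canonical_conformers()
  cref <- ctab[match(conf_name, ctab$name), ]
  ring_noise <- array(stats::rnorm(6L * 3L * n), dim = c(6L, 3L, n))

  C2 <- g$O2 + 1.43 * g$C2_dir
  coords <- array(NA_real_, dim = c(nrow(top), 3L, n))
  # coords[i, , ] is 3 x n; a length-3 vector recycles column-wise, an n x 3
  # matrix is assigned transposed
  put_fixed <- function(key, v) coords[ai[key], , ] <<- v
  put <- function(key, mat) coords[ai[key], , ] <<- t(mat)
  from <- function(origin, d, u)
    sweep(outer(d, u), 2L, origin, `+`)

  put_fixed("HEX.O2", g$O2)
  put_fixed("HEX.C2", C2)
  put_fixed("LYS.NZ", g$NZ)
  put_fixed("HEX.O3", g$O3)
  put_fixed("HEX.O4", g$O4)
  put("TYR.OH", from(g$O2, dmat[, 1L], g$u_tyr))
  put("THR.OG1", from(g$O2, dmat[, 2L], g$u_thr))
  put("NAD.O2R", from(g$NZ, dmat[, 3L], g$u_rib1))
  put("NAD.O3R", from(g$NZ, dmat[, 3L] + 1.0, g$u_rib2))
  put("NAD.C4", from(C2, dmat[, 4L], g$u_hyd))
  # H2 via the triangle C2-H2-C4: |C2-H2| = 1.09, angle at H2 = sampled
  alpha <- deg2rad(hyd)
  gam <- asin(pmin(1, 1.09 * sin(alpha) / dmat[, 4L]))
  beta <- pi - alpha - gam
  put("HEX.H2", sweep(1.09 * (outer(cos(beta), g$u_hyd) +
                                outer(sin(beta), c(1, 0, 0))),
                      2L, C2, `+`))
  tgt <- function(nm) if (cfg$contacts[[nm]]$target == "O3") g$O3 else g$O4
  put("ASN.CG", from(tgt("asn_cg"), contact_d$asn_cg, g$u_asn))
  put("GLN.CD", from(tgt("gln_cd"), contact_d$gln_cd, g$u_gln))
  put("VAL.O", from(tgt("val_o"), contact_d$val_o, g$u_val))
  put("MET.O", from(tgt("met_o"), contact_d$met_o, g$u_met))
  # pyrophosphate quartet: O1, P1, O12 fixed; P2 realises the torsion (same
  # internal coordinates as pp_quartet(), vectorised over frames)
  o1 <- c(1.6 * cos(deg2rad(120)), 1.6 * sin(deg2rad(120)), 0)
  put_fixed("CDP.O1", o1 + g$pp_offset)
  put_fixed("CDP.P1", g$pp_offset)
  put_fixed("CDP.O12", c(1.6, 0, 0) + g$pp_offset)
  tau <- deg2rad(dih$values)
  half <- deg2rad(60)
  p2 <- cbind(1.6 + 1.6 * cos(half),
              1.6 * sin(half) * cos(tau),
              1.6 * sin(half) * sin(tau))
  put("CDP.P2", sweep(p2, 2L, g$pp_offset, `+`))
  # ring: in-plane positions fixed per atom, out-of-plane from the sampled
  # conformer's canonical Cremer-Pople coordinates (Q = 0.57), plus noise
  q2 <- 0.57 * sin(deg2rad(cref$theta))
  q3 <- 0.57 * cos(deg2rad(cref$theta))
  ring_rows <- ai["PYR.O5"]:ai["PYR.C5"]
  for (j in 0:5) {
    ang <- 2 * pi * j / 6
    z <- sqrt(1 / 3) * q2 * cos(deg2rad(cref$phi) + 4 * pi * j / 6) +
      sqrt(1 / 6) * q3 * (-1)^j
    row <- ring_rows[j + 1L]
    coords[row, 1L, ] <- 1.43 * sin(ang) + g$ring_offset[1L] +
      noise_sd * ring_noise[j + 1L, 1L, ]
    coords[row, 2L, ] <- 1.43 * cos(ang) + g$ring_offset[2L] +
      noise_sd * ring_noise[j + 1L, 2L, ]
    coords[row, 3L, ] <- z + g$ring_offset[3L] +
      noise_sd * ring_noise[j + 1L, 3L, ]
  }

  truth <- data.frame(
    frame = seq_len(n), plausible = plaus,
    d_tyr = dmat[, 1L], d_thr = dmat[, 2L], d_lys = dmat[, 3L],
    d_hydride = dmat[, 4L],
    dihedral = dih$values, dihedral_component = dih$component,
    conformer = conf_name, hydride_angle = hyd,
    stringsAsFactors = FALSE
  )
  for (nm in names(contact_ind))
    truth[[paste0("contact_", nm)]] <- contact_ind[[nm]]

  list(trajectory = md_trajectory(top, coords), truth = truth)
}

#' Generate a ring-only pucker trajectory
#'
#' Frames hold a single six-atom ring built at each sampled conformer's
#' canonical Cremer-Pople position (amplitude `Q`) plus isotropic coordinate
#' noise; ground-truth labels are recorded.  With zero noise,
#' [cremer_pople()] returns exactly the canonical `(theta, phi)` of each
#' label.
#'
#' @param menu data frame `(conformer, prob)`; names must be canonical.
#' @param n number of frames.
#' @param noise_sd isotropic coordinate noise SD in Angstrom.
#' @param Q puckering amplitude (default 0.57 Angstrom).
#' @param seed integer seed.
#' @return List with `trajectory` (6-atom ring topology) and `truth`
#'   (per-frame conformer labels).
#' @export
generate_ring_trajectory <- function(menu, n, noise_sd = 0.02, Q = 0.57,
                                     seed = 1L) {
  stopifnot(is.data.frame(menu), all(c("conformer", "prob") %in% names(menu)))
  ctab <- canonical_conformers()
  unknown <- setdiff(menu$conformer, ctab$name)
  if (length(unknown))
    stop("unknown conformer name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (abs(sum(menu$prob) - 1) > 1e-9)
    stop("menu probabilities must sum to 1", call. = FALSE)
  set.seed(seed)
  top <- md_topology(serial = 1:6,
                     name = c("O5", "C1", "C2", "C3", "C4", "C5"),
                     resname = "PYR", resid = 1L, chain = "A",
                     element = c("O", "C", "C", "C", "C", "C"))
  id <- sample.int(nrow(menu), n, replace = TRUE, prob = menu$prob)
  ref <- ctab[match(menu$conformer[id], ctab$name), ]
  coords <- array(NA_real_, dim = c(6L, 3L, n))
  for (f in seq_len(n))
    coords[, , f] <- build_ring(Q, ref$theta[f], ref$phi[f]) +
      noise_sd * matrix(stats::rnorm(18L), 6L, 3L)
  list(trajectory = md_trajectory(top, coords),
       truth = data.frame(frame = seq_len(n),
                          conformer = menu$conformer[id],
                          stringsAsFactors = FALSE))
}
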