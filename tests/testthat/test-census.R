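bindings <- synthetic_bindings()

test_that("the canonical criteria build with 3.5 A cutoffs and clear errors", {
  cs <- default_sdr_criteria(bindings)
  expect_s3_class(cs, "criterion_set")
  expect_length(cs$criteria, 4L)
  expect_equal(unname(vapply(cs$criteria, `[[`, 0, "cutoff")), rep(3.5, 4))
  expect_equal(cs$criteria[[3]]$reduction, "min")

  b2 <- bindings
  b2$lys_nz <- NULL
  expect_error(default_sdr_criteria(b2), "lys_nz")

  cs2 <- default_sdr_criteria(bindings, cutoffs = list(hydride = 4.0))
  expect_equal(cs2$criteria[[4]]$cutoff, 4.0)

  cs3 <- default_sdr_criteria(bindings, lys_ribose = "both")
  expect_length(cs3$criteria, 5L)
})

test_that("frame verdicts follow the <= boundary semantics", {
  cs <- default_sdr_criteria(bindings)

  sf <- site_frame(d_tyr = 3.0, d_thr = 3.0, d_lys = 3.0, d_hyd = 3.4)
  v <- evaluate_frame(sf$frame, sf$topology, cs)
  expect_true(v$plausible)
  expect_equal(unname(v$distances), c(3.0, 3.0, 3.0, 3.4), tolerance = 1e-9)

  sf2 <- site_frame(d_tyr = 4.8)
  v2 <- evaluate_frame(sf2$frame, sf2$topology, cs)
  expect_false(v2$plausible)
  expect_false(v2$pass[["tyr_oh_o2"]])
  expect_true(all(v2$pass[c("thr_og_o2", "lys_nz_ribose", "hydride")]))

  sf3 <- site_frame(d_tyr = 3.5, d_thr = 3.5, d_lys = 3.5, d_hyd = 3.5)
  expect_true(evaluate_frame(sf3$frame, sf3$topology, cs)$plausible)
})

test_that("the lysine criterion takes the minimum over the ribose oxygens", {
  cs <- default_sdr_criteria(bindings)
  # d_lys places O2R at d and O3R at d + 1: at d = 3.2 only one oxygen is in
  # reach, which suffices under the min-over-pairs reading
  sf <- site_frame(d_lys = 3.2)
  v <- evaluate_frame(sf$frame, sf$topology, cs)
  expect_true(v$pass[["lys_nz_ribose"]])
  expect_equal(unname(v$distances[["lys_nz_ribose"]]), 3.2, tolerance = 1e-9)
})

test_that("census equals a brute-force frame-by-criterion loop", {
  cfg <- synthetic_config(n_frames = 100, fraction_plausible = 0.3,
                          seed = 19)
  ens <- generate_ensemble(cfg)
  cs <- default_sdr_criteria(bindings)
  cen <- census(ens$trajectory, cs)

  brute <- logical(n_frames(ens$trajectory))
  for (f in seq_along(brute)) {
    fr <- get_frame(ens$trajectory, f)
    ok <- TRUE
    for (cr in cs$criteria) {
      probe <- resolve_selection(ens$trajectory$topology, cr$probe)
      target <- resolve_selection(ens$trajectory$topology, cr$target)
      dmin <- Inf
      for (p in probe) for (t in target)
        dmin <- min(dmin, sqrt(sum((fr[p, ] - fr[t, ])^2)))
      if (dmin > cr$cutoff) ok <- FALSE
    }
    brute[f] <- ok
  }
  expect_identical(cen$verdicts$plausible, brute)
  expect_identical(cen$fraction, mean(brute))
  expect_identical(cen$n_plausible, sum(brute))
})

test_that("raising any cutoff never decreases the plausible fraction", {
  ens <- generate_ensemble(synthetic_config(n_frames = 400,
                                            fraction_plausible = 0.2,
                                            seed = 23))
  for (role in c("tyr_oh_o2", "thr_og_o2", "lys_nz_ribose", "hydride")) {
    prev <- -1
    for (cut in c(2.5, 3.0, 3.5, 4.5, 6.0)) {
      ovr <- stats::setNames(list(cut), role)
      cen <- census(ens$trajectory, default_sdr_criteria(bindings,
                                                         cutoffs = ovr))
      expect_gte(cen$fraction, prev)
      prev <- cen$fraction
    }
  }
})

test_that("conjunction bound: fraction never exceeds any marginal", {
  ens <- generate_ensemble(synthetic_config(n_frames = 500,
                                            fraction_plausible = 0.15,
                                            seed = 29))
  cen <- census(ens$trajectory, default_sdr_criteria(bindings))
  expect_lte(cen$fraction, min(cen$marginals) + 1e-12)
  expect_true(cen$ci["lower"] <= cen$fraction &&
                cen$fraction <= cen$ci["upper"])
})

test_that("a planted plausible fraction is recovered within 3 binomial SE", {
  n <- 10000
  p <- 0.05
  ens <- generate_ensemble(synthetic_config(n_frames = n,
                                            fraction_plausible = p,
                                            seed = 37))
  cen <- census(ens$trajectory, default_sdr_criteria(bindings))
  expect_lt(abs(cen$fraction - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("contact censuses label their denominators and refuse empty ones", {
  cfg <- synthetic_config(n_frames = 4000, fraction_plausible = 0.5,
                          contacts = list(
                            asn_cg = list(prob = 0.10, cutoff = 4.0,
                                          target = "O3"),
                            gln_cd = list(prob = 1.00, cutoff = 4.0,
                                          target = "O4"),
                            val_o = list(prob = 0.03, cutoff = 3.5,
                                         target = "O3"),
                            met_o = list(prob = 0.01, cutoff = 3.5,
                                         target = "O4")),
                          seed = 41)
  ens <- generate_ensemble(cfg)
  cen <- census(ens$trajectory, default_sdr_criteria(bindings))

  always <- contact_spec("gln_cd", atom_select(resname = "GLN", name = "CD"),
                         atom_select(resname = "HEX", name = "O4"),
                         cutoff = 4.0)
  ct <- contact_census(ens$trajectory, always,
                       verdicts = cen$verdicts$plausible)
  expect_equal(ct$fraction_all, 1)
  expect_equal(ct$fraction_plausible, 1)

  planted <- contact_spec("asn_cg", atom_select(resname = "ASN", name = "CG"),
                          atom_select(resname = "HEX", name = "O3"),
                          cutoff = 4.0)
  ct2 <- contact_census(ens$trajectory, planted)
  se <- sqrt(0.10 * 0.90 / cfg$n_frames)
  expect_lt(abs(ct2$fraction_all - 0.10), 3 * se)
  # contact planted independently of class: plausible-frame fraction agrees
  ct3 <- contact_census(ens$trajectory, planted,
                        verdicts = cen$verdicts$plausible)
  se_p <- sqrt(0.10 * 0.90 / ct3$n_plausible)
  expect_lt(abs(ct3$fraction_plausible - 0.10), 3 * se_p)

  need_verdicts <- contact_spec("asn_cg",
                                atom_select(resname = "ASN", name = "CG"),
                                atom_select(resname = "HEX", name = "O3"),
                                cutoff = 4.0,
                                denominator = "plausible-frames")
  expect_error(contact_census(ens$trajectory, need_verdicts),
               "requires per-frame verdicts")
  expect_error(contact_census(ens$trajectory, planted,
                              verdicts = rep(FALSE, cfg$n_frames)),
               "undefined fraction")
})

test_that("hydride-angle statistics require an explicit hydrogen", {
  sf <- site_frame(hydride_angle = 138.3)
  traj <- md_trajectory(sf$topology, sf$frame)
  hs <- hydride_angle_stats(traj,
                            atom_select(resname = "HEX", name = "C2"),
                            atom_select(resname = "HEX", name = "H2"),
                            atom_select(resname = "NAD", name = "C4"))
  expect_equal(hs$mean, 138.3, tolerance = 1e-6)

  sf180 <- site_frame(hydride_angle = 180)
  traj180 <- md_trajectory(sf180$topology, sf180$frame)
  hs180 <- hydride_angle_stats(traj180,
                               atom_select(resname = "HEX", name = "C2"),
                               atom_select(resname = "HEX", name = "H2"),
                               atom_select(resname = "NAD", name = "C4"))
  expect_equal(hs180$max, 180, tolerance = 1e-6)

  expect_error(
    hydride_angle_stats(traj, atom_select(resname = "HEX", name = "C2"),
                        atom_select(resname = "HEX", name = "O2"),
                        atom_select(resname = "NAD", name = "C4")),
    "missing hydrogen")

  ens <- generate_ensemble(synthetic_config(
    n_frames = 4000, hydride_angle = list(mean = 135, sd = 8), seed = 43))
  hs2 <- hydride_angle_stats(ens$trajectory,
                             atom_select(resname = "HEX", name = "C2"),
                             atom_select(resname = "HEX", name = "H2"),
                             atom_select(resname = "NAD", name = "C4"))
  expect_lt(abs(hs2$mean - 135), 3 * 8 / sqrt(4000))
})
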