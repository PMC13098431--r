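---
title: "Geometric censuses of epimerase conformational ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric censuses of epimerase conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdcensus)
```

## The model

NAD-dependent sugar-nucleotide 2-epimerases of the short-chain
dehydrogenase/reductase (SDR) superfamily invert a sugar stereocentre by a
two-step oxidation–reduction: the catalytic tyrosine acts as general base on
the reactive hydroxyl while a hydride transfers between the substrate carbon
and the nicotinamide C4 of the tightly bound NAD⁺; the transient keto sugar
then rotates and is re-reduced from the opposite face.  In an MD ensemble of
the Michaelis complex, the chemistry-competent subpopulation can be defined
purely geometrically.  `mdcensus` formalises that definition as a
*criterion set*: a conjunction of heavy-atom distance criteria, by default

1. Tyr-OH ⋯ sugar O2 ≤ 3.5 Å (catalytic base in reach of the reactive
   hydroxyl),
2. Thr-OG ⋯ sugar O2 ≤ 3.5 Å (the triad threonine positioning the same
   oxygen),
3. Lys-NZ ⋯ nicotinamide-ribose hydroxyl oxygens ≤ 3.5 Å (lysine lowering
   the tyrosine pKa through the ribose), and
4. C4(NAD) ⋯ sugar C2 ≤ 3.5 Å (hydride donor–acceptor distance).

A frame passing all criteria is *catalytically plausible*; the census
reports the ensemble fraction with a Wilson 95% confidence interval
(`stats::prop.test(..., correct = FALSE)`, which computes exactly the Wilson
score interval) together with per-criterion marginal pass fractions.  Two
readings of criterion 3 exist because "the ribose hydroxyl oxygen atoms"
does not say whether one or both oxygens must be engaged; the package
defaults to the weaker either-oxygen (minimum over pairs) reading and
offers the stricter both-oxygens variant (`lys_ribose = "both"`), which adds
one criterion per oxygen.  Distances are compared with `<=` semantics: a
frame exactly at the cutoff passes.

The hydride-transfer *angle* C2–H2–C4(NAD) is deliberately a reported
statistic, not a criterion: published plausible fractions for this enzyme
class are defined by distances alone, with the angle quoted separately
(typically ~130–140° on average).  An optional angle gate exists for
sensitivity analyses but is off by default.  The angle requires an explicit
H2 in the topology; the package never reconstructs hydrogens.

Contact censuses (probe atom to sugar C3/C4 hydroxyl oxygens) use 4.0 Å for
side-chain amide carbons — the amide N/O orientation cannot be assigned from
heavy atoms, so the carbon is probed with a laxer cutoff — and 3.5 Å for
backbone carbonyl oxygens.  Published contact percentages mix two
denominators (all frames vs plausible frames), so `contact_census()` always
computes and labels both and refuses an empty denominator rather than
reporting zero.

## Ring puckering

Six-membered ring conformations are described by Cremer–Pople coordinates:
amplitude $Q$ and sphere angles $(\theta, \phi)$ obtained from the
out-of-plane displacements $z_j$ relative to the mean plane through the
geometric centre, with the normal taken from the two weighted lattice
vectors $R' = \sum_j r_j \sin(2\pi(j-1)/6)$ and
$R'' = \sum_j r_j \cos(2\pi(j-1)/6)$.  The ring atom order is fixed to
O5, C1, C2, C3, C4, C5 with the phase origin at O5 — conformer labels are
meaningless without this convention — under which the ⁴C₁ chair maps to the
north pole ($\theta = 0$).  `build_ring()` is the exact inverse transform
(used heavily by the generator and the round-trip tests), placing atoms
clockwise (viewed from $+z$) on a circle of radius 1.43 Å, a mean pyranose
bond projection that only affects synthetic geometry, never analysis.

Conformer assignment minimises great-circle distance to the canonical
38-reference table: chairs at the poles, six boats and six twist-boats
alternating every 30° of $\phi$ on the equator, and twelve envelopes plus
twelve half-chairs on the $\theta \approx 54.74°/125.26°$ circles —
envelopes at $\phi$ multiples of 60°, half-chairs offset by 30°.  The
table was derived here directly from the $z_j$ patterns of the analytic
coordinates (e.g. $\phi = 0°$, $\theta = 90°$ raises O5 and C3: the
³,⁰B boat), which also fixes the label spellings (ring oxygen written `0`,
as in `0S2`, `1H0`).  Exact ties break lexicographically by name.  Rings
with $Q < 0.1$ Å are reported planar/unassigned because $\phi$ is
numerically unstable as $Q \to 0$.

A relabeling law worth knowing: starting the atom ordering one position
later leaves $Q$ invariant, advances $\phi$ by 120° for the equatorial
component and negates $q_3$ (so $\theta \mapsto 180° - \theta$).  The test
suite asserts the equatorial case explicitly.

## Free-energy landscapes and torsion statistics

Landscapes are plain histogram estimates
$F = -k_B T \ln(P/P_{\max})$ with $k_B = 0.0019872041$ kcal mol⁻¹ K⁻¹,
referenced so the most populated bin is zero.  The default temperature is
333 K, matching a thermophile simulation protocol; at that temperature
$k_B T \approx 0.662$ kcal/mol, and two bins whose counts differ by a
factor of $e$ differ by exactly $k_B T$ — a closed form the tests exploit.
Default bin widths are 5° for dihedral axes (matching the ±5° granularity
at which torsion modes are conventionally quoted) and 0.25 Å for distance
axes; neither is dictated by theory and both are configurable.  Bins are
half-open $[lo, hi)$ with the top edge closed; dihedral axes wrap at ±180°
on a fixed grid so that shifting all samples by 360° provably changes
nothing.

Empty bins are masked, never given $+\infty$ or a pseudo-count: unsampled
regions carry no barrier-height information and fabricating one would bias
basin analyses.  `find_basins()` returns unmasked local minima
(8-neighbourhood), collapses equal-$F$ plateaus to the lowest-index bin for
determinism, and reports bin centres without sub-bin interpolation — at
0.25 Å bins that matches the precision at which basin positions are
usually quoted.  No reweighting estimators (WHAM/MBAR), kernel smoothing or
block-average error bars are provided; those are out of scope.

Torsion series get standard directional statistics: circular mean and mean
resultant length, with the mean flagged undefined when the resultant is
numerically zero (antipodal samples), and a wrapped-histogram mode with
deterministic tie-breaking towards the smaller absolute angle.  Von Mises
sampling uses the Best–Fisher (1979) rejection algorithm implemented
in-package (no circular-statistics dependency is available at run time);
its correctness is pinned by the Bessel-ratio identity
$E[R] \to I_1(\kappa)/I_0(\kappa)$ and by the analytic 1D free-energy
profile $k_B T\,\kappa(1 - \cos(x - \mu))$ that a large von Mises sample
must reproduce.

## Geometry kernels and structure comparison

Distances, angles and dihedrals are exact Euclidean kernels; dihedrals use
the atan2 formulation in the IUPAC sign convention (clockwise positive
viewed along the central bond) with range $(-180°, 180°]$ and trans mapped
to $+180°$ so the trans state has a single representation.  No
periodic-boundary imaging is applied anywhere: the measured quantities are
short-range active-site distances and input frames are assumed imaged.
One property surprised us enough to document: the torsion is *invariant*
under full reversal of the quartet (i–j–k–l vs l–k–j–i); the sign flips
under mirror inversion, not reversal.  Both facts are asserted against an
independent triple-product oracle and `bio3d::torsion.xyz`.

Kabsch superposition is implemented on base `svd()` with the determinant
correction that excludes reflections, so mirror-image point sets retain a
positive RMSD; collinear point sets are rejected (the rotation is
underdetermined).  `residue_displacement()` superposes on a caller-chosen
fit region and reports per-residue mean displacements of a selection —
the standard induced-fit profile for loop-ordering questions — with
residues absent from one structure reported as `NA`, never silently zero.
Outlier-rejecting iterative superposition is intentionally absent: RMSDs
quoted over varying atom counts in the literature imply rejection schemes
of external software that this package does not attempt to reproduce.

## The synthetic generator: what it emulates and what it does not

`generate_ensemble()` emits a 25-atom pseudo-active-site topology and
constructs coordinates so that each frame *realises* its sampled ground
truth exactly: criterion atoms sit along fixed, mutually non-parallel unit
directions from their targets at radial distances drawn from truncated
normals (inverse-CDF sampling, so the truncation is exact rather than
bounded-retry), the pyrophosphate quartet realises its sampled torsion
through internal coordinates, the hydride angle is realised by a triangle
construction at fixed C2–H2 bond length (1.09 Å), and the pyranose ring is
rebuilt from each sampled conformer's canonical Cremer–Pople position
(Q = 0.57 Å) plus isotropic noise.  Class membership is therefore a hard
guarantee — plausible frames satisfy all criteria, unproductive frames
violate their designated criteria with a 10⁻⁶ Å margin against the
boundary-inclusive cutoff — while the *fraction* of plausible frames is
Bernoulli, so recovery tests are statistical at 3 binomial standard errors.

Study conditions are built into two presets and are not tuning knobs:
`"cdp-glc-like"` (plausible fraction 0.016, torsion mode 170°, pucker menu
97% ⁴C₁ with a 3% ⁰S₂ excursion) and `"cdp-man-like"` (0.0418, 130°, menu
80% ⁴C₁ with ¹H₀/¹E/¹H₂ populations and a minor ⁰S₂ cluster).  Fractions
and torsion modes are the published ensemble statistics for the two
substrates; the menu weights and the torsion concentration (κ = 130,
circular SD ≈ 5°, matching the ±5° mode width) are this package's choices
where only qualitative descriptions ("dominant chair", "additional
populations toward...") are published.  Contact probabilities default to
the published contact percentages; they are planted independently of the
plausibility class, which the tests exploit to check both denominators.

What the generator does **not** emulate: force-field energetics, solvent,
correlated frame-to-frame dynamics, realistic covalent geometry between the
placed atoms (the criteria are deliberately decoupled), protein-wide
coordinates, or any coupling between pucker state and catalytic
plausibility.  Passing tests therefore demonstrate that the *analysis
machinery* is correct and unbiased on data with known structure — not that
any particular physical ensemble has a given plausible fraction.  Analyses
of real trajectories should load them through `read_structure()` /
`read_trajectory()` (multi-model PDB, XYZ, optionally DCD via `bio3d`).

## Numerical and design choices

* **Frame indexing is 1-based** throughout, the R ecosystem convention.
* **Altloc policy**: records with alternate location `' '`/`'A'` are kept,
  others dropped with a single warning — the standard single-conformer
  convention.
* **Planarity**: `cremer_pople()` flags $Q < 10^{-4}$ Å as planar at the
  coordinate level; conformer assignment applies its own 0.1 Å threshold.
* **Wilson intervals** rather than Wald: the censused fractions are small
  (1–5%) where Wald intervals under-cover badly.
* **Determinism**: the generator consumes the R RNG only through its
  `seed`; identical config + seed reproduces trajectories bitwise, and
  `run_pipeline()` writes byte-identical TSVs on reruns (each report echoes
  the full effective configuration in its header).
* **Problem sizes** used by the tests and the acceptance script: 100-frame
  ensembles for exact brute-force classifier equivalence, 10⁴ frames ×
  20 seeds for fraction recovery and Wilson coverage, 24 × 10³ frames (a
  full pooled production ensemble) for the headline censuses, 10⁵–10⁶
  von Mises draws for mode and free-energy limits.
* **Command-line surface**: the package is driven from R; `run_pipeline()`
  orchestrates simulate → census → torsion → pucker → landscape → report
  with per-stage TSV outputs, and the individual stages are ordinary
  exported functions.

## Known limitations

No periodic-boundary treatment; no mmCIF or AMBER-topology parsing (DCD
coordinates require a separately supplied topology); no furanose (five-ring)
puckering; no hydrogen-bond detection with angular terms; no free-energy
error bars; the contact census is a distance threshold, not an interaction
energy.  The synthetic geometry is non-physical by design, as discussed
above.
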