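# mdcensus

Geometric census and conformational analysis of enzyme–substrate molecular
dynamics (MD) ensembles, written for NAD-dependent sugar-nucleotide
epimerases and other short-chain dehydrogenase/reductase (SDR) enzymes.

## The problem

SDR-type epimerases invert a sugar stereocentre by transient oxidation:
a catalytic tyrosine abstracts the hydroxyl proton while a hydride moves
from the substrate carbon to the nicotinamide C4 of NAD⁺.  Whether a given
MD snapshot could support that chemistry is a *geometric* question: the
catalytic triad (Thr/Ser–Tyr–Lys) and the hydride donor–acceptor pair must
sit within hydrogen-bonding / transfer distance simultaneously.  `mdcensus`
turns that question into a reproducible statistic:

* **Plausibility census** — a frame is *catalytically plausible* when every
  heavy-atom distance criterion of the canonical SDR alcohol-oxidation
  geometry holds at its cutoff (default 3.5 Å, boundary inclusive):
  Tyr-OH⋯O2, Thr-OG⋯O2, Lys-NZ⋯(nicotinamide-ribose OH) and
  C4(NAD)⋯C2.  The ensemble fraction is reported with its Wilson 95%
  confidence interval and per-criterion marginals.
* **Contact censuses** — probe→sugar-hydroxyl contact fractions (e.g.
  side-chain amide carbons at 4.0 Å, backbone carbonyl oxygens at 3.5 Å)
  under explicitly labelled denominators (all frames vs plausible frames).
* **Torsion statistics** — circular mean/resultant and wrapped-histogram
  modes of dihedral series such as the pyrophosphate O1–P1–O12–P2 torsion.
* **Ring puckering** — Cremer–Pople coordinates (Q, θ, φ) with IUPAC
  conformer assignment against the canonical 38-reference table
  (ring order O5, C1…C5; ⁴C₁ at θ = 0°), plus the inverse construction.
* **Free-energy landscapes** — 1D/2D histogram estimates
  F = −k_B·T·ln(P/P_max) over collective variables, with masked empty bins
  and deterministic basin detection.
* **Structure comparison** — Kabsch superposition (reflections excluded)
  and per-residue displacement profiles for induced-fit analysis.
* **Synthetic ensembles** — a deterministic generator that plants known
  plausible fractions, contact probabilities, von Mises torsion mixtures
  and pucker menus into a pseudo-active-site topology, so every analysis
  stage is validated against ground truth without any MD data.

Multi-model PDB and XYZ trajectories are read and written natively
(gzip accepted); binary DCD trajectories are supported when `bio3d` is
installed (`dcd_supported()`).

## Worked example

```r
library(mdcensus)

cfg <- synthetic_preset("cdp-man-like", n_frames = 10000, seed = 1)
ens <- generate_ensemble(cfg)
cs  <- default_sdr_criteria(synthetic_bindings())
census(ens$trajectory, cs)
#> census 'canonical SDR alcohol oxidation': 435 / 10000 frames plausible
#> (4.350%), Wilson 95% CI [3.967%, 4.768%]
#> per-criterion marginal pass fractions:
#>   tyr_oh_o2                4.35% (cutoff 3.50 A)
#>   thr_og_o2               43.67% (cutoff 3.50 A)
#>   lys_nz_ribose           44.26% (cutoff 3.50 A)
#>   hydride                  4.35% (cutoff 3.50 A)
```

The preset plants a 4.18% plausible fraction; the census recovers 4.35%,
inside the Wilson interval — the designated failing criteria (Tyr and
hydride) carry the low marginals, the others pass in roughly half of the
unproductive frames by chance.  Puckering of the attached pyranose ring:

```r
pucker_series(ens$trajectory, atom_select(resname = "PYR"))
#> pucker_series over 10000 frames; 0 planar/unassigned
#>   4C1   79.88%
#>   1H0    6.87%
#>   1E     5.22%
#>   1H2    5.15%
#>   0S2    2.88%
```

A full run (`run_pipeline(cfg, "out/")`) adds the torsion mode, the 2D
free-energy surface over (torsion, Tyr-OH⋯O2 distance) with its basins, the
contact censuses under both denominators, and writes diff-able TSV reports.

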