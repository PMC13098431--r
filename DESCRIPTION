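Package: mdcensus
Title: Geometric Census and Conformational Analysis of Enzyme-Substrate
    Molecular Dynamics Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of molecular-dynamics conformational ensembles of
    NAD-dependent sugar-nucleotide epimerases and related short-chain
    dehydrogenase/reductase (SDR) enzymes.  Classifies trajectory frames as
    catalytically plausible by heavy-atom distance criteria of the canonical
    SDR alcohol-oxidation geometry and reports ensemble fractions with Wilson
    confidence intervals; measures contact censuses, hydride-transfer angle
    statistics and pyrophosphate torsion distributions (circular statistics,
    wrapped-histogram modes); computes Cremer-Pople puckering coordinates and
    IUPAC conformer assignments for pyranose rings; estimates one- and
    two-dimensional free-energy landscapes from histogrammed collective
    variables with basin detection; and performs Kabsch superposition with
    per-residue displacement profiling.  Includes readers and writers for
    multi-model PDB and XYZ trajectories (optionally DCD via 'bio3d'), a
    deterministic synthetic-ensemble generator with planted ground truth for
    validating every analysis stage, and enzyme-kinetics helpers (specific
    activity from time courses, fold changes, turnover numbers).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    bio3d,
    jsonlite,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
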