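Package: peptisite
Title: Peptide Binding-Site Mapping, Rigidity Perturbation and Binding
    Isotherm Analysis for Receptor-Peptide Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to locate where a short peptide binds on a receptor dimer
    from ensembles of structures and to quantify the consequences of binding.
    Provides multi-model PDB input/output and Kabsch superposition; synthetic
    generators for receptor-dimer/peptide diffusion ensembles with planted
    binding sites and for microscale thermophoresis (MST) dilution-series
    isotherms; centre-of-mass occupancy grids and per-residue hydrogen-bond/
    salt-bridge propensities; Ward clustering of bound poses with
    sum-of-squares merge heights; body-bar pebble-game rigidity analysis with
    constraint dilution and per-residue stability perturbation upon ligand
    removal; and one-site binding-isotherm fitting with ligand depletion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
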