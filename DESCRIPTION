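Package: pulmofat
Title: Automated CT Pulmonary Fat Attenuation Volumetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fully automated quantification of pulmonary fat attenuation
    volume (CTpfav) and the pulmonary fat index (PFI) from chest CT volumes
    with co-registered lung and lobe label masks. Fat-isodense voxels are
    extracted by Hounsfield-unit windowing inside the lung mask and converted
    to physical volumes; a spacing-aware exact signed Euclidean distance
    transform partitions the lung into subpleural and nonsubpleural
    compartments, and lobar aggregation reports per-lobe and per-lobe-group
    indices. Includes a deterministic synthetic chest-CT phantom generator
    with analytically known ground truth for validation, a cohort simulator,
    and the nonparametric cohort-comparison battery (D'Agostino-Pearson
    normality, Kruskal-Wallis omnibus, Dunn post hoc) used to compare
    patient groups.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
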