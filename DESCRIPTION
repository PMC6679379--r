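Package: vestisyn
Title: Vestibular Synapse Deafferentation and Vestibulo-Ocular Function Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantification of vestibular primary-synapse deafferentation and
    repair from two-channel 3D confocal stacks, together with the associated
    vestibulo-ocular functional read-outs. Provides a synthetic ground-truth
    generator for ribbon-synapse puncta fields calibrated against cumulative
    pre/post-synaptic distance profiles, a confocal stack renderer with
    anisotropic PSF and Poisson noise, 3D Laplacian-of-Gaussian puncta
    detection, directed nearest-neighbour distance and colocalisation
    metrics, simulators and analysers for angular vestibulo-ocular reflex
    (aVOR) gain, maculo-ocular reflex (MOR) bias during off-vertical axis
    rotation, and spontaneous vestibular nystagmus rate, plus group-level
    statistics (Dunnett, repeated-measures ANOVA) and a timecourse
    correlation grid builder.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    signal,
    multcomp,
    car
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
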