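Package: seccg
Title: Coarse-Grained Simulation of Sec-Facilitated Protein Translocation
    and Membrane Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-dimensional coarse-grained (CG) simulator of
    co-translational protein translocation and membrane integration through
    the Sec translocon. Amino-acid sequences are mapped 3:1 onto bead-spring
    chains carrying water-membrane transfer free energies and charges; the
    nascent chain evolves by overdamped Langevin dynamics in an implicit
    membrane, coupled to stochastic lateral-gate switching of the translocon
    and explicit ribosomal elongation. Includes single-bead translocation
    potentials of mean force by numerical quadrature, parameter fitting
    against reference PMF curves, and assay pipelines for H-segment
    integration probabilities, apparent free energies of integration, and
    transmembrane-domain topogenesis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    seqinr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
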