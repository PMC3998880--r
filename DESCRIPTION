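Package: encomr
Title: Elastic Network Contact Models for Coarse-Grained Protein Normal Mode Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained normal mode analysis of protein structures with an
    elastic network contact model (ENCoM) whose long-range springs are modulated
    by atom-type-weighted surfaces in contact between residues, alongside the
    classical anisotropic network model (ANM), the Gaussian network model (GNM),
    the four-term Go-like spring tensor model (STeM) and a non-specific contact
    variant.  Provides the standard observables derived from the spectral
    decomposition of the stiffness matrix (crystallographic b-factor prediction,
    conformational overlap against a target structure, vibrational entropy
    differences used as an entropic score for the effect of mutations) together
    with the statistical machinery to benchmark them: through-origin regression,
    bootstrap resampling, mutation classification, self-consistency bias and
    error, linear model combination and a grid search over the force-constant
    parameters.  Includes deterministic synthetic-structure generators (bead
    chains, ideal helices, hinged two-domain toys with single-sphere side
    chains) so the whole pipeline is testable without external structure
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils
Suggests:
    MASS,
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
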