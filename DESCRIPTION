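Package: pkautoinit
Title: Automated Data-Driven Initial Estimates for Population Pharmacokinetic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes data-driven initial estimates for population
    pharmacokinetic base models from longitudinal concentration-time
    datasets in the NONMEM/nlmixr2 column convention, including sparse
    designs. Structural starting values (CL, V, Ka) are derived by an
    adaptive single-point method, naive pooled non-compartmental analysis
    with Wagner-Nelson absorption estimation, and graphical
    one-compartment methods; the best candidate (including per-parameter
    hybrids) is selected by relative root mean squared error against the
    individual-level data. Michaelis-Menten (Vmax, Km) and two-/three-
    compartment parameters (Vp, Q, Vp2, Q2) are initialized by
    simulation-based parameter sweeping, and residual-error and
    inter-individual-variability starting values are obtained by
    terminal-phase regression with a fixed-fraction fallback. A synthetic
    dataset generator emulating rich, semi-sparse and sparse sampling
    designs is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
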