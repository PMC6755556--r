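Package: ligeff
Title: Unit-Aware Ligand Efficiency Metrics and Their Alternatives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes, audits and replaces ligand-efficiency metrics used in
    drug discovery. Implements the classical size-scaled metrics (LE, BEI,
    eta_bind, LEAN, FQ) together with an explicit account of their dependence
    on the standard concentration used to express affinity, a dimensional
    algebra for equilibrium constants and free-energy decompositions,
    group-efficiency analysis of structural transformations with additivity
    checks, fragment-to-lead pair analysis with concentration-unit-independent
    efficiency measures, and residual-based normalization of affinity against
    molecular size by ordinary least squares. Deterministic synthetic-data
    generators and a small command-line interface are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), ChemmineR, jsonlite, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
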