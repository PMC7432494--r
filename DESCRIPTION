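Package: ubconform
Title: Open/Closed Conformational Populations of Lys48-Linked Ubiquitin
    Chains from Amide Chemical Shifts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts assigned 1H-15N HSQC peak positions of Lys48-linked
    polyubiquitin chains into per-unit open/closed state fractions by
    chemical-shift projection against monomeric-ubiquitin (open) and cyclic
    diubiquitin (closed) reference spectra, and inverts those fractions into
    populations of discrete chain conformational states under a
    matching-based state model with a simplex constraint. Includes Sparky and
    CSV peak-list I/O, collinearity diagnostics, exact and non-negative
    least-squares solvers, linear-programming feasibility bounds for
    underdetermined chains, bootstrap uncertainty propagation, and a seeded
    synthetic peak-list generator implementing the fast-exchange
    population-weighted shift model.
License: MIT
Encoding: UTF-8
Imports:
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
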