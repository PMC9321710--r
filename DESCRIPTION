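Package: moeko
Title: Multiobjective Evolutionary Strain Design on Stoichiometric Metabolic Models
Version: 0.1.0
Authors@R: person("moeko", "developers", role = c("aut", "cre"),
    email = "moeko@example.org")
Description: Constraint-based strain design for growth-coupled chemical
    overproduction. Represents genome-scale metabolic models (SBML-FBC or
    COBRA JSON), parses and evaluates gene-protein-reaction Boolean rules,
    simulates gene knockouts and heterologous pathway knock-ins, and solves
    flux balance analysis (FBA), flux variability analysis (FVA) and
    parsimonious FBA (pFBA) with a built-in bounded-variable simplex solver.
    A non-dominated-sorting multiobjective evolutionary algorithm searches
    binary gene-deletion vectors for Pareto-optimal strains under growth,
    yield and productivity objectives with growth-floor, cofactor flux-sum,
    essential-gene and synthetic-lethal constraints, and reports strain
    tables with cofactor production and chromosome co-location of knockouts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    xml2,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
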