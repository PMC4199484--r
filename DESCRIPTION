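Package: gaplik
Title: Likelihood-Based Annotation and Gap Filling for Genome-Scale
    Metabolic Models
Version: 0.1.0
Authors@R:
    person("gaplik", "developers", email = "gaplik@example.org",
           role = c("aut", "cre"))
Description: Computes per-gene annotation likelihoods from BLAST
    sequence-homology evidence against a high-confidence reference,
    propagates them to reaction likelihoods through a biochemistry
    template (annotation to role to complex to reaction) with assembly
    of Boolean gene-protein-reaction (GPR) rules, and uses the inverted
    likelihoods as objective weights in mixed-integer gap filling of
    draft metabolic networks. Includes flux balance and flux
    variability analysis on a built-in simplex solver, targeted and
    iterative gap-filling workflows with reaction-sensitivity pruning,
    knockout-lethality and Biolog-style phenotype simulation, and
    seeded synthetic fixture generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
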