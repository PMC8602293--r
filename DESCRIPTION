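Package: irdtriage
Title: Variant Prioritization, Splice-Assay Interpretation and Case
    Resolution for Inherited Retinal Disease Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a whole-genome-sequencing variant interpretation
    workflow for inherited retinal disease (IRD) cohorts: gene-panel
    restricted prioritization of coding, noncanonical splice-site,
    deep-intronic, structural and repeat-expansion variants from annotated
    variant records; selection of splice-assay candidates from SpliceAI
    delta scores and Alamut-style algorithm score pairs; quantification of
    in vitro minigene/midigene splice-assay band tables into percent
    wild-type and allele-severity classes; breakpoint microhomology and
    gene-disruption assessment for structural variants; repeat-expansion
    classification; and case-level resolution into solved, likely-solved
    and unsolved with cohort summaries. Ships a deterministic
    literature-derived 100-case fixture and a seeded synthetic cohort
    generator with planted causal genotypes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
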