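Package: agescore
Title: Composite Aging-Marker Panel Scoring for Cultured Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies eight classical cellular-aging markers (gamma-H2A.X
    foci, telomere length by monochrome multiplex qPCR, H3K9Me3 and Lamin B1
    immunofluorescence, SA-beta-galactosidase staining, p21/p16 expression,
    SASP cytokines, nuclear morphology) from raw assay measurements, calls
    each marker significant against pooled controls by one-way ANOVA followed
    by Dunnett's many-to-one comparison with an aging-direction filter, and
    aggregates the binary calls into primary, antagonistic and full AgeScores
    per cell line.  Includes condition-wise marker frequency tables, marker
    pattern comparison, score-donor-age correlation, a seeded synthetic-data
    generator emulating the replicate structure of fibroblast aging panels,
    and a transcribed 27-line reference call matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    multcomp,
    mvtnorm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
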