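Package: hemidel
Title: Mendelian-Error Mapping and Transmission Analysis of a Mosaic
    Hemizygous Deletion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps a large hemizygous deletion from SNP-array genotypes by
    Mendelian-inconsistency (opposite-homozygote) scanning in a sire-progeny
    design, characterizes the deletion breakpoints from sequencing-derived
    evidence (read-depth ratio segmentation, discordant read pairs, clipped-read
    junction consensus with micro-insertion recovery), and quantifies its
    transmission: chi-square tests for sex-ratio distortion and departure from
    autosomal-dominant expectation, cross-stage transmission comparisons,
    germline mosaicism estimation from sperm-FISH counts with doubled
    Clopper-Pearson intervals, and an upper bound on embryonic-death timing
    from artificial-insemination records.  A seeded synthetic-cohort generator
    emulating a mosaic founder bull with a male-lethal deletion provides ground
    truth for parameter-recovery testing, so no external data are required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
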