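Package: bsamap
Title: Bulked Segregant Analysis by Pooled Sequencing: Simulation and
    Causal-Variant Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of mapping-by-sequencing experiments
    for recessive mutants recovered from chemically mutagenized plant
    populations.  Simulates a mutagenized line crossed to wild type and
    selfed to a segregating BC1F2 population, phenotype-selected DNA pools,
    and pooled short-read evidence at induced SNP sites; then recovers the
    causal coding mutation from per-pool allele frequencies via quality
    filtering, windowed allele-frequency scans along chromosomes, and
    strand/phase-aware coding-effect annotation.  Companion calculators
    implement chlorophyll-fluorescence parameters (Fv/Fm, PhiPSII, qP, NPQ),
    Mendelian segregation tests, the analytic pooled allele-frequency
    expectations for a single recessive locus, and dry-matter carbon
    isotope discrimination.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
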