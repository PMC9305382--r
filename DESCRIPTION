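Package: sangermeth
Title: Per-Cytosine Methylation Quantification from Direct Bisulfite Sanger
    Sequencing of Plant Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies position-specific 5-methylcytosine levels from
    direct bisulfite Sanger sequencing chromatogram signals using the
    peak-ratio estimators mC = C/(C+T) (forward reads) and mC = G/(G+A)
    (reverse reads), classifies cytosines into the three plant methylation
    contexts (CG, CHG, CHH) on both strands, computes general and specific
    methylation summaries per sample, compares cell lines with Welch
    t-tests, detects runs of methylated cytosines (hotspots), profiles
    promoter pyrimidine (Y) content in sliding windows with Y-region
    detection, scans promoters against a built-in IUPAC cis-element
    catalog, and reports overlap between predicted transcription factor
    binding sites and methylated cytosines. Includes in-silico bisulfite
    conversion, degenerate (Y/R) primer and amplicon design, a
    bisulfite-aware pairwise aligner, a fully seeded synthetic-data
    generator producing two-cell-line methylomes and noisy four-channel
    traces with known ground truth, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
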