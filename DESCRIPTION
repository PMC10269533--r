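Package: ttrcensus
Title: Census of Transmembrane Transcription Regulators in Prokaryotic
    Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies transmembrane transcription regulators (TTRs) --
    membrane-anchored one-component regulators carrying both a DNA-binding
    domain and at least one transmembrane helix -- from proteome FASTA
    files, profile-HMM domain-hit tables and TMHMM-style transmembrane
    segment files.  Scores transmembrane regions for length and accessible
    surface area per residue (flagging lipid-raft propensity at or below
    172 Angstrom^2 per residue), detects hybrid TTRs that additionally
    carry two-component core domains, and aggregates genome-, taxon- and
    cohort-level abundance statistics with taxonomy parsed from GTDB-style
    strings.  Includes a hydropathy-based transmembrane predictor used
    when no segment file is supplied, a synthetic-cohort generator with
    ground truth for end-to-end testing, and a scripted pipeline producing
    tab-separated tables plus a statistics report.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
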