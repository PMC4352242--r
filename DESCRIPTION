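Package: txforge
Title: De Novo Transcriptome QC, Orthology and Enrichment Toolkit
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-assembly analysis of de novo transcriptomes for non-model
    species, built around a ground-truthed two-species, multi-tissue
    transcriptome simulator. Provides running-sum 3' quality trimming with
    read-pair synchronization, a k-mer seeded read-to-transcript mapper with
    per-base coverage, coverage filtering and assembly metrics (N50, reads
    used), core-gene recovery assessment, greedy incremental clustering by
    global identity, hexamer Markov-model coding-region prediction with
    eclipsed-ORF exclusion, reciprocal-best-hit orthology with
    identity/divergence statistics, tissue- and species-enriched transcript
    discovery, hypergeometric GO over-representation with
    Benjamini-Hochberg correction, and Pfaffl qPCR ratio statistics with
    Wilcoxon-Mann-Whitney testing, orchestrated by a deterministic
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
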