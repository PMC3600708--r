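Package: msatools
Title: High-Throughput Microsatellite Genotyping from Capillary
    Electrophoresis Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for automated microsatellite (short tandem repeat)
    genotyping from multiplexed capillary electrophoresis fragment
    analysis. Implements an 11-marker multiplex panel (the NCI
    mononucleotide markers Bat25 and Bat26 plus nine dinucleotide
    markers), peak detection with minimum peak half-width filtering,
    internal ROX size-standard matching, Local Southern fragment sizing
    (with Global Southern and third-order least-squares comparators),
    stutter-aware allele calling with integer bins (+/- 0.5 bp offset)
    and the 0.95 mono cut-off rule, process quality control (per-allele
    sizing %CV, percent deviation from expected genotypes, control
    charts), microsatellite instability classification, loss of
    heterozygosity scoring, and Mendelian lineage checks. Includes a
    ground-truthed electropherogram simulator (stutter, adenylation,
    spectral bleed-through, spikes, nonspecific products) for validation
    and benchmarking, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
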