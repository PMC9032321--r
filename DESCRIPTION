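Package: visirna
Title: Virus Discovery Triage, Viral Genome Annotation and vsiRNA Signature
    Profiling for Insect Metatranscriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for characterising insect-specific RNA
    viruses from metatranscriptome and small-RNA sequencing data. Implements
    candidate-virus contig triage from homology-search tables (E-value and
    length screening, best-hit host-versus-virus reclassification), ORF
    prediction with UTR segmentation and overlapping-ORF detection for
    positive-sense RNA virus genomes, zero-mismatch exact mapping of collapsed
    18-30 nt small-RNA reads onto both genome strands, and the standard
    virus-derived siRNA (vsiRNA) signature statistics: size-by-strand
    distributions, 5'-terminal nucleotide composition in unique and
    total-read weightings, A/U bias, positional 5'-start profiles and
    hotspot calling. A synthetic-data module generates genomes, small-RNA
    libraries and triage fixtures with known ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
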