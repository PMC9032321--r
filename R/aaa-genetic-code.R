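# Genetic-code constants, loaded before everything else that uses them.

stop_codons <- c("TAA", "TAG", "TGA")

# Standard genetic code, DNA codons -> one-letter amino acids ("*" = stop).
codon_table <- local({
  bases <- c("T", "C", "A", "G")
  codons <- apply(
    expand.grid(bases, bases, bases, stringsAsFactors = FALSE)[, 3:1],
    1, paste0,
    collapse = ""
  )
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"
  ), "")[[1]]
  stats::setNames(aa, codons)
})
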