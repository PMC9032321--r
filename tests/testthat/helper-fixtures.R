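# Shared fixture builders and independent oracles. Oracles deliberately use
# different algorithmic routes (regex scans, per-ATG walks, C string search)
# than the package implementation they check.

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

random_seq_tbl <- function(n_records, min_len = 10, max_len = 80) {
  tibble::tibble(
    id = sprintf("s%03d", seq_len(n_records)),
    description = ifelse(runif(n_records) < 0.5, "", "some description text"),
    residues = vapply(
      sample(min_len:max_len, n_records, replace = TRUE),
      random_dna, character(1)
    )
  )
}

random_read_tbl <- function(n_reads, min_len = 18, max_len = 30) {
  lens <- sample(min_len:max_len, n_reads, replace = TRUE)
  tibble::tibble(
    id = sprintf("r%05d", seq_len(n_reads)),
    residues = vapply(lens, random_dna, character(1)),
    quality = strrep("I", lens)
  )
}

# Brute-force exact mapping oracle: C-level fixed-string search (gregexpr)
# over every position of both strands, independent of the seed-and-verify
# index. Overlapping occurrences are found by rescanning from each hit + 1.
all_occurrences <- function(q, subject) {
  hits <- integer()
  from <- 1L
  repeat {
    h <- regexpr(q, substr(subject, from, nchar(subject)), fixed = TRUE)
    if (h == -1L) break
    hits <- c(hits, from + h - 1L)
    from <- from + h # allow overlapping matches
  }
  hits
}

naive_map <- function(reads_tbl, genome, genome_id = "genome") {
  rc_genome <- visirna::revcomp(genome)
  L <- nchar(genome)
  res <- vector("list", nrow(reads_tbl))
  for (i in seq_len(nrow(reads_tbl))) {
    q <- reads_tbl$residues[[i]]
    n <- nchar(q)
    plus <- all_occurrences(q, genome) - 1L
    minus_rc <- all_occurrences(q, rc_genome) - 1L
    minus <- L - minus_rc - n # map revcomp-strand position to + strand
    n_p <- length(plus); n_m <- length(minus)
    if (n_p + n_m == 0L) next
    res[[i]] <- list(
      left = c(plus, minus),
      strand = rep(c("sense", "antisense"), c(n_p, n_m)),
      i = rep(i, n_p + n_m), n = n
    )
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(tibble::tibble(
      residues = character(), count = integer(), genome_id = character(),
      left = integer(), strand = character(), five_prime_pos = integer()
    ))
  }
  left <- unlist(lapply(res, `[[`, "left"))
  strand <- unlist(lapply(res, `[[`, "strand"))
  ridx <- unlist(lapply(res, `[[`, "i"))
  n <- unlist(lapply(res, function(r) rep(r$n, length(r$left))))
  tibble::tibble(
    residues = reads_tbl$residues[ridx],
    count = reads_tbl$count[ridx],
    genome_id = genome_id,
    left = left,
    strand = strand,
    five_prime_pos = ifelse(strand == "sense", left, left + n - 1L)
  ) |> dplyr::arrange(left, strand, residues)
}

# Independent ORF oracle: walk forward from every ATG in every frame/strand
# to the first in-frame stop, then keep the earliest ATG per stop.
oracle_orfs <- function(genome, min_protein_len, strands = c("+", "-")) {
  scan <- function(seq, strand_label) {
    L <- nchar(seq)
    found <- list()
    for (s0 in 0:(L - 3)) {
      if (substr(seq, s0 + 1, s0 + 3) != "ATG") next
      p <- s0
      repeat {
        if (p + 3 > L) break
        cod <- substr(seq, p + 1, p + 3)
        if (p > s0 && cod %in% c("TAA", "TAG", "TGA")) {
          found[[length(found) + 1L]] <- c(start = s0, end = p + 3)
          break
        }
        p <- p + 3
      }
    }
    if (!length(found)) {
      return(tibble::tibble(start = integer(), end = integer(),
                            strand = character()))
    }
    df <- tibble::as_tibble(do.call(rbind, found))
    df |>
      dplyr::group_by(end) |>
      dplyr::summarise(start = min(start), .groups = "drop") |>
      dplyr::filter((end - start) / 3 - 1 >= min_protein_len) |>
      dplyr::mutate(start = as.integer(start), end = as.integer(end),
                    strand = strand_label) |>
      dplyr::select(start, end, strand)
  }
  L <- nchar(genome)
  res <- list()
  if ("+" %in% strands) res[["+"]] <- scan(genome, "+")
  if ("-" %in% strands) {
    m <- scan(visirna::revcomp(genome), "-")
    m <- dplyr::mutate(m, start2 = L - end, end = L - start, start = start2)
    res[["-"]] <- dplyr::select(m, start, end, strand)
  }
  dplyr::arrange(dplyr::bind_rows(res), start, end, strand)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
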