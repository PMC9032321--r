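# Small-RNA preprocessing and zero-mismatch mapping: length extraction,
# collapsing of identical reads, and exact-match placement of collapsed
# reads on both strands of a viral genome via a seed-and-verify substring
# index (hash of fixed-length seeds, full-length verification), so lookup
# cost per occurrence is independent of genome length.

#' Extract reads by length
#'
#' Keeps reads with `min_len <= length <= max_len` (inclusive bounds, the
#' conventional 18-30 nt siRNA window), preserving input order.
#'
#' @param reads Read tibble (see [read_fastq()]).
#' @param min_len,max_len Length bounds in nt.
#' @return The filtered read tibble.
#' @export
extract_by_length <- function(reads, min_len = 18L, max_len = 30L) {
  stopifnot(min_len <= max_len)
  reads[nchar(reads$residues) >= min_len & nchar(reads$residues) <= max_len, ]
}

#' Collapse identical reads
#'
#' Deduplicates reads into (sequence, count) pairs. Reads containing `N` are
#' dropped before collapsing (exact matching with `N` is undefined); the
#' number dropped is recorded in the `dropped_n` attribute and messaged.
#'
#' @param reads Read tibble.
#' @return Tibble with `residues` and `count`, sorted by descending count
#'   then lexicographic residues; attribute `dropped_n` = reads dropped for
#'   containing `N`.
#' @export
collapse_reads <- function(reads) {
  has_n <- stringr::str_detect(reads$residues, "N")
  dropped <- sum(has_n)
  if (dropped > 0L) {
    message(sprintf("collapse_reads: dropped %d read(s) containing N", dropped))
  }
  kept <- reads$residues[!has_n]
  tab <- table(kept)
  out <- tibble(
    residues = names(tab),
    count = as.integer(tab)
  ) |>
    arrange(desc(.data$count), .data$residues)
  attr(out, "dropped_n") <- dropped
  out
}

#' Build an exact-match substring index over a genome
#'
#' Seed-and-verify structure: every `min_len`-mer of the (+) strand is hashed
#' to its start offsets; a query is located by looking up its `min_len`-nt
#' prefix and verifying the full-length substring, on the (+) strand for the
#' query itself and for its reverse complement (an antisense placement).
#' Genome positions containing `N` never match (seeds with `N` are not
#' indexed and verification is literal).
#'
#' @param genome One-row sequence tibble or a single DNA string.
#' @param min_len,max_len Query length range the index answers (inclusive).
#' @return A `substring_index` object.
#' @export
build_index <- function(genome, min_len = 18L, max_len = 30L) {
  g <- as_genome(genome)
  L <- nchar(g$residues)
  if (L < min_len) {
    abort(sprintf("genome length %d is shorter than min_len %d", L, min_len))
  }
  starts <- 0:(L - min_len) # 0-based offsets
  seeds <- substring(g$residues, starts + 1L, starts + min_len)
  ok <- !stringr::str_detect(seeds, "N")
  seed_map <- new.env(parent = emptyenv(), size = sum(ok) * 2L)
  pos_by_seed <- split(starts[ok], seeds[ok])
  for (k in names(pos_by_seed)) assign(k, pos_by_seed[[k]], envir = seed_map)
  structure(
    list(genome_id = g$id, residues = g$residues, genome_length = L,
         min_len = as.integer(min_len), max_len = as.integer(max_len),
         seed_map = seed_map),
    class = "substring_index"
  )
}

#' @export
print.substring_index <- function(x, ...) {
  cat(sprintf(
    "<substring_index> %s: %d nt, query range %d-%d nt\n",
    x$genome_id, x$genome_length, x$min_len, x$max_len
  ))
  invisible(x)
}

# All 0-based start offsets where `query` occurs literally on the indexed
# (+) strand. Seed lookup, then full-length verification.
index_occurrences <- function(index, query) {
  n <- nchar(query)
  seed <- substr(query, 1L, index$min_len)
  cand <- get0(seed, envir = index$seed_map, ifnotfound = integer())
  if (!length(cand) || n == index$min_len) return(cand)
  cand <- cand[cand + n <= index$genome_length]
  if (!length(cand)) return(cand)
  full <- substring(index$residues, cand + 1L, cand + n)
  cand[full == query & !stringr::str_detect(full, "N")]
}

#' Map collapsed reads with zero mismatches
#'
#' Reports every exact occurrence of each read on either strand (multi-mapped
#' reads yield one record per site); a read matching neither strand yields no
#' record. For a sense placement the read's 5' nucleotide sits at the left
#' end of the matched span; for an antisense placement (read equal to the
#' reverse complement of the genome substring) it sits at the right end.
#'
#' @param reads Collapsed-read tibble from [collapse_reads()] (columns
#'   `residues`, `count`), lengths within the index's range.
#' @param index A [build_index()] object.
#' @return Mapping tibble sorted by (`left`, `strand`): `residues`, `count`,
#'   `genome_id`, `left` (0-based leftmost offset of the span), `strand`
#'   (`sense`/`antisense`) and `five_prime_pos` (0-based genome offset of the
#'   read's 5' base).
#' @export
map_exact <- function(reads, index) {
  lens <- nchar(reads$residues)
  if (any(lens < index$min_len | lens > index$max_len)) {
    abort(sprintf(
      "read length outside the indexed range %d-%d nt",
      index$min_len, index$max_len
    ))
  }
  rc <- revcomp(reads$residues)
  n_reads <- nrow(reads)
  occ_left <- vector("list", 2L * n_reads)
  occ_read <- integer(2L * n_reads)
  occ_sense <- logical(2L * n_reads)
  k <- 0L
  for (i in seq_len(n_reads)) {
    sense_left <- index_occurrences(index, reads$residues[[i]])
    if (length(sense_left)) {
      k <- k + 1L
      occ_left[[k]] <- sense_left; occ_read[[k]] <- i; occ_sense[[k]] <- TRUE
    }
    anti_left <- index_occurrences(index, rc[[i]])
    if (length(anti_left)) {
      k <- k + 1L
      occ_left[[k]] <- anti_left; occ_read[[k]] <- i; occ_sense[[k]] <- FALSE
    }
  }
  if (k == 0L) {
    return(tibble(
      residues = character(), count = integer(), genome_id = character(),
      left = integer(), strand = character(), five_prime_pos = integer()
    ))
  }
  occ_left <- occ_left[seq_len(k)]
  reps <- lengths(occ_left)
  ridx <- rep(occ_read[seq_len(k)], reps)
  is_sense <- rep(occ_sense[seq_len(k)], reps)
  left <- unlist(occ_left, use.names = FALSE)
  tibble(
    residues = reads$residues[ridx],
    count = reads$count[ridx],
    genome_id = index$genome_id,
    left = left,
    strand = ifelse(is_sense, "sense", "antisense"),
    five_prime_pos = ifelse(is_sense, left, left + lens[ridx] - 1L)
  ) |>
    arrange(.data$left, .data$strand, .data$residues)
}

#' Write mapping records as a 1-based TSV
#'
#' @param mappings Mapping tibble from [map_exact()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
mapping_report <- function(mappings, path) {
  mappings |>
    mutate(left_1based = .data$left + 1L,
           five_prime_pos_1based = .data$five_prime_pos + 1L) |>
    select("residues", "count", "genome_id", "left_1based", "strand",
           "five_prime_pos_1based") |>
    write_report_tsv(path)
}
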