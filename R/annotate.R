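# ORF prediction and genome segmentation for positive-sense RNA virus
# genomes: maximal ATG-initiated, stop-terminated spans (longest-per-stop),
# translation under the standard genetic code, UTR lengths from the
# outermost (+)-strand ORFs, and interval-based overlap detection between
# ORFs (the hallmark nidovirus ORF3/ORF4 arrangement).
#
# Coordinates are 0-based half-open throughout; [annotation_report()] emits
# 1-based inclusive rows for interoperability with GFF-style tooling.

#' Predict open reading frames
#'
#' An ORF is a maximal ATG-initiated span ending in a stop codon in a fixed
#' frame and strand, with translated length of at least `min_protein_len`
#' amino acids. Per stop codon only the longest ORF is reported (the first
#' ATG after the previous in-frame stop); nested downstream ATGs are
#' suppressed. Defaults (`min_protein_len = 100`, `strands = "+"`) suit
#' positive-sense RNA virus genomes.
#'
#' @param genome One-row sequence tibble or a single DNA string.
#' @param min_protein_len Minimum protein length in amino acids.
#' @param strands Character vector, subset of `c("+", "-")`.
#' @return A tibble sorted by `start`: `start`, `end` (0-based half-open
#'   genome offsets), `strand`, `frame` (0/1/2 on the reading strand) and
#'   `protein`.
#' @examples
#' find_orfs("ATGAAATAG", min_protein_len = 1)
#' @export
find_orfs <- function(genome, min_protein_len = 100L, strands = "+") {
  stopifnot(min_protein_len >= 1, all(strands %in% c("+", "-")))
  g <- as_genome(genome)
  L <- nchar(g$residues)
  if (L < 6L) {
    return(tibble(start = integer(), end = integer(), strand = character(),
                  frame = integer(), protein = character()))
  }
  scan_strand <- function(seq, strand) {
    res <- list()
    for (frame in 0:2) {
      n_codon <- (nchar(seq) - frame) %/% 3L
      if (n_codon < 2L) next
      starts <- frame + 3L * (seq_len(n_codon) - 1L)
      codons <- substring(seq, starts + 1L, starts + 3L)
      is_stop <- codons %in% stop_codons
      is_atg <- codons == "ATG"
      # segment index between consecutive stops; first ATG in each segment
      # that is followed (within the segment) by a stop opens the ORF
      seg <- cumsum(c(FALSE, head(is_stop, -1L)))
      for (s in which(is_stop)) {
        seg_id <- seg[[s]]
        cand <- which(is_atg & seg == seg_id)
        cand <- cand[cand < s]
        if (!length(cand)) next
        first_atg <- cand[[1]]
        aa_len <- s - first_atg # codons between ATG and stop, exclusive
        if (aa_len - 0L < min_protein_len) next
        res[[length(res) + 1L]] <- list(
          s0 = starts[[first_atg]], e0 = starts[[s]] + 3L, frame = frame
        )
      }
    }
    res
  }
  out <- list()
  if ("+" %in% strands) {
    for (o in scan_strand(g$residues, "+")) {
      out[[length(out) + 1L]] <- tibble(
        start = o$s0, end = o$e0, strand = "+", frame = o$frame
      )
    }
  }
  if ("-" %in% strands) {
    rc <- revcomp(g$residues)
    for (o in scan_strand(rc, "-")) {
      # map revcomp coordinates back to genome coordinates
      out[[length(out) + 1L]] <- tibble(
        start = L - o$e0, end = L - o$s0, strand = "-", frame = o$frame
      )
    }
  }
  if (!length(out)) {
    return(tibble(start = integer(), end = integer(), strand = character(),
                  frame = integer(), protein = character()))
  }
  orfs <- bind_rows(out) |> arrange(.data$start, .data$end, .data$strand)
  orfs$protein <- vapply(seq_len(nrow(orfs)), function(i) {
    cds <- substr(g$residues, orfs$start[[i]] + 1L, orfs$end[[i]])
    if (orfs$strand[[i]] == "-") cds <- revcomp(cds)
    translate(cds)
  }, character(1))
  orfs
}

#' Translate a coding sequence
#'
#' Standard genetic code; the terminal stop codon is dropped from the
#' protein. Codons containing `N` translate to `X` (ambiguous assembly
#' positions are tolerated); an internal stop codon or a length not
#' divisible by 3 is an error.
#'
#' @param cds Single DNA string, length divisible by 3, ending in a stop
#'   codon (or not — a terminal stop is dropped when present).
#' @return One-letter amino-acid string.
#' @examples
#' translate("ATGAAATAG")
#' @export
translate <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    abort(sprintf("CDS length %d is not divisible by 3", n))
  }
  starts <- seq(1L, n, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(codon_table[codons])
  aa[is.na(aa)] <- "X" # codons containing N (or other ambiguity)
  n_codon <- length(aa)
  internal_stop <- which(aa[-n_codon] == "*")
  if (length(internal_stop)) {
    abort(sprintf("internal stop codon at codon index %d", internal_stop[[1]]))
  }
  if (n_codon && aa[[n_codon]] == "*") aa <- aa[-n_codon]
  paste(aa, collapse = "")
}

#' Segment a genome into 5' UTR, ORFs and 3' UTR
#'
#' UTR lengths are measured from the outermost (+)-strand ORFs:
#' `utr5_length` is the start offset of the first ORF and `utr3_length` is
#' `genome_length` minus the end of the last ORF.
#'
#' @param genome_length Genome length in nt.
#' @param orfs ORF tibble from [find_orfs()]; at least one (+)-strand ORF.
#' @param genome_id Optional genome id carried into the result.
#' @return A `genome_annotation` object: list with `genome_id`,
#'   `genome_length`, `orfs`, `utr5_length`, `utr3_length`, `overlaps`.
#' @export
segment_genome <- function(genome_length, orfs, genome_id = "genome") {
  if (any(orfs$start < 0L) || any(orfs$end > genome_length)) {
    abort("ORF exceeds genome bounds")
  }
  plus <- orfs[orfs$strand == "+", , drop = FALSE]
  if (nrow(plus) == 0L) abort("segment_genome requires at least one (+)-strand ORF")
  structure(
    list(
      genome_id = genome_id,
      genome_length = as.integer(genome_length),
      orfs = arrange(orfs, .data$start, .data$end),
      utr5_length = min(plus$start),
      utr3_length = as.integer(genome_length) - max(plus$end),
      overlaps = detect_overlaps(arrange(orfs, .data$start, .data$end))
    ),
    class = "genome_annotation"
  )
}

#' Detect overlapping ORF pairs
#'
#' Reports every pair of ORFs whose genomic intervals intersect by more
#' than 0 nt (half-open intervals: adjacent ORFs do not overlap).
#'
#' @param orfs ORF tibble sorted by `start`.
#' @return Tibble with `orf_i`, `orf_j` (row indices into `orfs`, i < j) and
#'   `overlap_nt`.
#' @export
detect_overlaps <- function(orfs) {
  n <- nrow(orfs)
  out <- tibble(orf_i = integer(), orf_j = integer(), overlap_nt = integer())
  if (n < 2L) return(out)
  stopifnot(!is.unsorted(orfs$start))
  pairs <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ov <- min(orfs$end[[i]], orfs$end[[j]]) - max(orfs$start[[i]], orfs$start[[j]])
      if (ov > 0L) {
        pairs[[length(pairs) + 1L]] <- tibble(
          orf_i = i, orf_j = j, overlap_nt = as.integer(ov)
        )
      }
    }
  }
  if (length(pairs)) bind_rows(pairs) else out
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "<genome_annotation> %s: %d nt, %d ORF(s), 5'UTR %d nt, 3'UTR %d nt, %d overlap(s)\n",
    x$genome_id, x$genome_length, nrow(x$orfs), x$utr5_length, x$utr3_length,
    nrow(x$overlaps)
  ))
  invisible(x)
}

#' Tidy a genome annotation into feature rows
#'
#' One row per feature (`five_prime_UTR`, `CDS`, `three_prime_UTR`) with
#' 0-based half-open `start`/`end`.
#'
#' @param x A `genome_annotation`.
#' @param ... Unused.
#' @return A tibble of features.
#' @method tidy genome_annotation
#' @export
tidy.genome_annotation <- function(x, ...) {
  plus <- x$orfs[x$orfs$strand == "+", , drop = FALSE]
  bind_rows(
    tibble(
      feature = "five_prime_UTR", start = 0L, end = x$utr5_length,
      strand = "+", length = x$utr5_length
    ),
    tibble(
      feature = "CDS", start = x$orfs$start, end = x$orfs$end,
      strand = x$orfs$strand, length = x$orfs$end - x$orfs$start
    ),
    tibble(
      feature = "three_prime_UTR", start = max(plus$end),
      end = x$genome_length, strand = "+", length = x$utr3_length
    )
  ) |>
    mutate(genome_id = x$genome_id, .before = 1)
}

#' One-row summary of a genome annotation
#'
#' @param x A `genome_annotation`.
#' @param ... Unused.
#' @return A one-row tibble: genome id/length, ORF count, UTR lengths,
#'   overlap count.
#' @method glance genome_annotation
#' @export
glance.genome_annotation <- function(x, ...) {
  tibble(
    genome_id = x$genome_id, genome_length = x$genome_length,
    n_orfs = nrow(x$orfs), utr5_length = x$utr5_length,
    utr3_length = x$utr3_length, n_overlaps = nrow(x$overlaps)
  )
}

#' Write a genome annotation as a 1-based feature TSV
#'
#' GFF-flavoured rows (`seqid`, `source`, `type`, `start`, `end`, `strand`)
#' with 1-based inclusive coordinates.
#'
#' @param annotation A `genome_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
annotation_report <- function(annotation, path) {
  feats <- tidy(annotation) |>
    filter(.data$length > 0L) |>
    mutate(
      seqid = .data$genome_id, source = "visirna", type = .data$feature,
      start = .data$start + 1L, end = .data$end
    ) |>
    select("seqid", "source", "type", "start", "end", "strand")
  write_report_tsv(feats, path)
}
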