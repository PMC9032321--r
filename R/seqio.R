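# Readers and writers for the plain-text formats the pipeline touches:
# FASTA, 4-line FASTQ, 12/13-column tabular homology hits ("outfmt 6" layout),
# and TSV reports. Parsers are line-based so that malformed input produces
# the specific, actionable errors documented on each reader.

#' Read a FASTA file into a sequence tibble
#'
#' Multi-line sequences are concatenated, residues are uppercased, and any
#' letter outside `{A,C,G,T,N}` (IUPAC ambiguity codes included) is mapped to
#' `N` with a warning, because downstream exact matching treats `N` as
#' never-matching. The record id is the header text up to the first
#' whitespace; the remainder is kept as `description`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `residues`.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a first", "ACGT", ">b", "NN", "NN"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort(sprintf("no records in FASTA file '%s'", path))
  is_header <- startsWith(lines, ">")
  if (!is_header[[1]]) {
    abort(sprintf("FASTA parse error in '%s': sequence line before any header", path))
  }
  rec <- cumsum(is_header)
  headers <- sub("^>", "", lines[is_header])
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(
    grepl("\\s", headers),
    sub("^\\S+\\s+", "", headers), ""
  )
  seqs <- vapply(
    split(lines[!is_header], rec[!is_header]),
    paste0, character(1),
    collapse = ""
  )
  # records with a header but no sequence lines are empty -> invalid
  residues <- character(length(headers))
  residues[as.integer(names(seqs))] <- seqs
  if (any(!nzchar(residues))) {
    abort(sprintf(
      "FASTA parse error in '%s': empty sequence for record(s) %s",
      path, paste(id[!nzchar(residues)], collapse = ", ")
    ))
  }
  if (anyDuplicated(id)) {
    abort(sprintf(
      "duplicate FASTA ids in '%s': %s",
      path, paste(unique(id[duplicated(id)]), collapse = ", ")
    ))
  }
  tibble(id = id, description = description,
         residues = sanitize_residues(residues, "FASTA"))
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with columns `id`, `residues` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line-wrap width for residues (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  desc <- if ("description" %in% names(seqs)) seqs$description else ""
  header <- paste0(">", seqs$id, ifelse(nzchar(desc), paste0(" ", desc), ""))
  wrapped <- lapply(seqs$residues, function(s) {
    starts <- seq(1L, nchar(s), by = width)
    substring(s, starts, pmin(starts + width - 1L, nchar(s)))
  })
  out <- unlist(purrr::map2(header, wrapped, c), use.names = FALSE)
  writeLines(out, path)
  invisible(path)
}

#' Read a 4-line-per-record FASTQ file
#'
#' Residues are uppercased (non-ACGTN mapped to `N` with a warning); the
#' quality string is kept verbatim. A record whose quality length differs
#' from its sequence length is a parse error naming the record id.
#'
#' @param path Path to a FASTQ file.
#' @return A tibble with columns `id`, `residues`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- read_text_lines(path)
  if (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0L) abort(sprintf("no records in FASTQ file '%s'", path))
  if (length(lines) %% 4L != 0L) {
    abort(sprintf(
      "FASTQ parse error in '%s': %d lines is not a multiple of 4 (truncated record?)",
      path, length(lines)
    ))
  }
  idx <- seq(1L, length(lines), by = 4L)
  head_l <- lines[idx]
  seq_l <- lines[idx + 1L]
  plus_l <- lines[idx + 2L]
  qual_l <- lines[idx + 3L]
  if (!all(startsWith(head_l, "@"))) {
    abort(sprintf("FASTQ parse error in '%s': record header not starting with '@'", path))
  }
  if (!all(startsWith(plus_l, "+"))) {
    abort(sprintf("FASTQ parse error in '%s': separator line not starting with '+'", path))
  }
  id <- sub("\\s.*$", "", sub("^@", "", head_l))
  bad <- nchar(seq_l) != nchar(qual_l)
  if (any(bad)) {
    abort(sprintf(
      "FASTQ parse error in '%s': sequence/quality length mismatch for record(s) %s",
      path, paste(id[bad], collapse = ", ")
    ))
  }
  tibble(id = id, residues = sanitize_residues(seq_l, "FASTQ"), quality = qual_l)
}

#' Write a read tibble to 4-line FASTQ
#'
#' @param reads Tibble with columns `id`, `residues` and optionally `quality`
#'   (missing quality is filled with `"I"`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "residues") %in% names(reads)))
  qual <- if ("quality" %in% names(reads)) {
    reads$quality
  } else {
    strrep("I", nchar(reads$residues))
  }
  stopifnot(all(nchar(qual) == nchar(reads$residues)))
  out <- as.vector(rbind(paste0("@", reads$id), reads$residues, "+", qual))
  writeLines(out, path)
  invisible(path)
}

hit_columns <- c(
  "query_id", "subject_id", "percent_identity", "aln_length", "mismatches",
  "gap_opens", "q_start", "q_end", "s_start", "s_end", "evalue", "bitscore",
  "subject_category"
)

#' Read tabular homology hits (12/13-column "outfmt 6" layout)
#'
#' Columns are `qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore`, optionally followed by a 13th
#' `subject_category` column (`viral`, `cellular` or `unknown`). Rows with 12
#' columns get `subject_category = "unknown"`. Coordinates stay 1-based
#' inclusive as in the source format.
#'
#' @param path Path to a tab-separated hits file.
#' @return A tibble with one row per alignment.
#' @export
read_tabular_hits <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(!(ncols %in% c(12L, 13L)))
  if (length(bad)) {
    abort(sprintf(
      "tabular hits parse error in '%s': line %d has %d columns (expected 12 or 13)",
      path, bad[[1]], ncols[[bad[[1]]]]
    ))
  }
  get <- function(i) vapply(fields, function(f) f[[i]], character(1))
  num <- function(i, what) {
    raw <- get(i)
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      abort(sprintf(
        "tabular hits parse error in '%s': non-numeric %s '%s' at line %d",
        path, what, raw[which(is.na(val))[1]], which(is.na(val))[1]
      ))
    }
    val
  }
  category <- vapply(
    fields, function(f) if (length(f) >= 13L) f[[13]] else "unknown", character(1)
  )
  bad_cat <- !(category %in% c("viral", "cellular", "unknown"))
  if (any(bad_cat)) {
    abort(sprintf(
      "tabular hits parse error in '%s': unknown subject_category '%s' at line %d",
      path, category[which(bad_cat)[1]], which(bad_cat)[1]
    ))
  }
  hits <- tibble(
    query_id = get(1), subject_id = get(2),
    percent_identity = num(3, "percent_identity"),
    aln_length = as.integer(num(4, "aln_length")),
    mismatches = as.integer(num(5, "mismatches")),
    gap_opens = as.integer(num(6, "gap_opens")),
    q_start = as.integer(num(7, "q_start")),
    q_end = as.integer(num(8, "q_end")),
    s_start = as.integer(num(9, "s_start")),
    s_end = as.integer(num(10, "s_end")),
    evalue = num(11, "evalue"),
    bitscore = num(12, "bitscore"),
    subject_category = category
  )
  if (any(hits$evalue < 0) || any(!is.finite(hits$bitscore)) ||
      any(hits$q_start > hits$q_end)) {
    abort(sprintf("tabular hits in '%s' violate field invariants", path))
  }
  hits
}

#' Write a tabular-hits tibble in the 13-column layout
#'
#' @param hits Tibble as returned by [read_tabular_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  stopifnot(all(hit_columns %in% names(hits)))
  rows <- do.call(paste, c(
    lapply(hits[hit_columns], function(col) {
      if (is.numeric(col)) format(col, scientific = NA, trim = TRUE, digits = 6) else col
    }),
    sep = "\t"
  ))
  writeLines(rows, path)
  invisible(path)
}

#' Write a report table as TSV
#'
#' Header line plus one row per record, columns in their tibble order,
#' numeric values rendered with 6 significant digits.
#'
#' @param table A data frame (all rows share the column set by construction).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(table, path) {
  if (!is.data.frame(table)) {
    abort("`table` must be a data frame (heterogeneous row sets are not representable).")
  }
  fmt <- lapply(table, function(col) {
    if (is.double(col)) {
      ifelse(is.na(col), "NA", format(signif(col, 6), trim = TRUE, scientific = NA))
    } else {
      as.character(col)
    }
  })
  lines <- c(
    paste(names(table), collapse = "\t"),
    if (nrow(table)) do.call(paste, c(fmt, sep = "\t"))
  )
  writeLines(lines, path)
  invisible(path)
}
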