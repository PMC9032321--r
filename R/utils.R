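# Internal helpers shared across modules. All genome coordinates inside the
# package are 0-based half-open; conversion to 1-based inclusive happens only
# in report writers.

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the `{A,C,G,T,N}` alphabet.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "AAAN"))
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", x))
}

# Coerce a genome argument to a single named sequence. Accepts a one-row
# sequence tibble (id, residues), a named length-1 character vector, or a bare
# string (id defaults to "genome").
as_genome <- function(genome) {
  if (is.data.frame(genome)) {
    if (nrow(genome) != 1L || !all(c("id", "residues") %in% names(genome))) {
      abort("`genome` must be a one-row tibble with columns `id` and `residues`.")
    }
    return(list(id = genome$id[[1]], residues = toupper(genome$residues[[1]])))
  }
  if (is.character(genome) && length(genome) == 1L) {
    id <- names(genome) %||% "genome"
    if (identical(id, "")) id <- "genome"
    return(list(id = id, residues = toupper(unname(genome))))
  }
  abort("`genome` must be a one-row sequence tibble or a single character string.")
}

# Map IUPAC ambiguity codes (and anything else outside ACGTN) to N, warning
# once per call. Downstream exact matching treats N as never-matching.
sanitize_residues <- function(x, context = "sequence") {
  x <- toupper(x)
  bad <- stringr::str_detect(x, "[^ACGTN]")
  if (any(bad)) {
    warn(sprintf(
      "%d %s record(s) contained non-ACGTN letters; mapped to N.",
      sum(bad), context
    ))
    x[bad] <- stringr::str_replace_all(x[bad], "[^ACGTN]", "N")
  }
  x
}

# Split raw text into lines tolerating CRLF and a missing trailing newline.
read_text_lines <- function(path) {
  raw <- readLines(path, warn = FALSE)
  sub("\r$", "", raw)
}

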