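# vsiRNA signature statistics over zero-mismatch mapping records: size-by-
# strand distributions in unique (each collapsed read once per site) and
# total (weighted by read count) weightings, 5'-terminal nucleotide
# composition reported in the RNA alphabet, A/U bias, per-offset 5'-start
# profiles, strand balance and moving-sum quantile hotspot calling.

srna_lengths <- 18:30

#' Size-by-strand distribution of mapped vsiRNAs
#'
#' @param mappings Mapping tibble from [map_exact()].
#' @param lengths Lengths to tabulate (absent lengths reported as 0).
#' @return Tibble with one row per (`length`, `strand`): `unique_count`
#'   (each collapsed read once per site) and `total_count` (weighted by read
#'   count).
#' @export
size_strand_distribution <- function(mappings, lengths = srna_lengths) {
  grid <- tidyr::expand_grid(length = as.integer(lengths),
                             strand = c("sense", "antisense"))
  if (nrow(mappings) == 0L) {
    return(mutate(grid, unique_count = 0L, total_count = 0L))
  }
  counts <- mappings |>
    mutate(length = nchar(.data$residues)) |>
    group_by(.data$length, .data$strand) |>
    summarise(unique_count = n(), total_count = sum(.data$count),
              .groups = "drop")
  grid |>
    left_join(counts, by = c("length", "strand")) |>
    mutate(unique_count = dplyr::coalesce(.data$unique_count, 0L),
           total_count = dplyr::coalesce(.data$total_count, 0L))
}

#' 5'-terminal nucleotide composition
#'
#' Fractions of A/C/G/U at the 5' terminus of the read (RNA alphabet: T is
#' reported as U), restricted to records of the given read length.
#'
#' @param mappings Mapping tibble from [map_exact()].
#' @param length Read length to analyse (default 21 nt, the canonical
#'   Dicer product length).
#' @param weighting `"unique"` (each record once) or `"total"` (weighted by
#'   read count).
#' @return Tibble with columns `base` (A/C/G/U) and `fraction` (summing to
#'   1; all-`NA` when no records of that length exist).
#' @export
five_prime_composition <- function(mappings, length = 21L,
                                   weighting = c("unique", "total")) {
  weighting <- match.arg(weighting)
  stopifnot(length %in% srna_lengths)
  rna_bases <- c("A", "C", "G", "U")
  m <- mappings[nchar(mappings$residues) == length, , drop = FALSE]
  if (nrow(m) == 0L) {
    return(tibble(base = rna_bases, fraction = NA_real_))
  }
  five <- chartr("T", "U", substr(m$residues, 1L, 1L))
  w <- if (weighting == "total") m$count else rep(1L, nrow(m))
  tot <- vapply(rna_bases, function(b) sum(w[five == b]), numeric(1))
  tibble(base = rna_bases, fraction = unname(tot) / sum(tot))
}

#' A/U bias of a 5'-terminal composition
#'
#' @param composition Tibble from [five_prime_composition()].
#' @return `fraction(A) + fraction(U)` (0.5 is the no-bias baseline under a
#'   uniform composition); `NA` for an all-`NA` composition.
#' @export
au_bias <- function(composition) {
  stopifnot(all(c("base", "fraction") %in% names(composition)))
  if (all(is.na(composition$fraction))) return(NA_real_)
  sum(composition$fraction[composition$base %in% c("A", "U")])
}

#' Per-offset 5'-start profile
#'
#' Total-weighted count of records whose 5' base sits at each genome offset,
#' split by strand.
#'
#' @param mappings Mapping tibble from [map_exact()].
#' @param genome_length Genome length in nt.
#' @return Tibble with one row per offset 0..`genome_length - 1`: `offset`,
#'   `sense`, `antisense`.
#' @export
positional_profile <- function(mappings, genome_length) {
  if (nrow(mappings) && any(mappings$five_prime_pos < 0L |
                            mappings$five_prime_pos >= genome_length)) {
    abort("five_prime_pos outside [0, genome_length)")
  }
  prof <- tibble(offset = 0:(genome_length - 1L), sense = 0, antisense = 0)
  for (s in c("sense", "antisense")) {
    m <- mappings[mappings$strand == s, , drop = FALSE]
    if (nrow(m)) {
      acc <- vapply(
        split(m$count, m$five_prime_pos), sum, numeric(1)
      )
      prof[[s]][as.integer(names(acc)) + 1L] <- acc
    }
  }
  prof
}

#' Total-weighted sense-strand fraction
#'
#' @param mappings Mapping tibble from [map_exact()].
#' @return Sense weight / total weight, or `NA` for an empty record set.
#' @export
strand_fraction <- function(mappings) {
  if (nrow(mappings) == 0L) return(NA_real_)
  sum(mappings$count[mappings$strand == "sense"]) / sum(mappings$count)
}

#' Call vsiRNA hotspots on one strand of a positional profile
#'
#' The per-offset counts are smoothed with a centred moving sum of width
#' `window`; offsets whose smoothed value is strictly positive and exceeds
#' the `quantile` quantile of all smoothed values are called, and called
#' offsets separated by at most `merge_gap` nt are merged into intervals.
#'
#' @param positional Profile tibble from [positional_profile()].
#' @param strand `"sense"` or `"antisense"`.
#' @param window Moving-sum width in nt.
#' @param quantile Quantile of smoothed values used as the call threshold.
#' @param merge_gap Maximum gap in nt between called offsets merged into one
#'   interval.
#' @return Tibble of hotspot intervals: `strand`, `start`, `end` (0-based
#'   half-open), `peak_count` (maximum smoothed value inside the interval).
#' @export
detect_hotspots <- function(positional, strand = c("sense", "antisense"),
                            window = 21L, quantile = 0.99, merge_gap = 10L) {
  strand <- match.arg(strand)
  x <- positional[[strand]]
  stopifnot(all(x >= 0))
  if (all(x == 0)) {
    return(tibble(strand = character(), start = integer(), end = integer(),
                  peak_count = double()))
  }
  smoothed <- moving_sum(x, window)
  thr <- stats::quantile(smoothed, quantile, names = FALSE, type = 7)
  called <- which(smoothed > thr & smoothed > 0) # 1-based indices
  if (!length(called)) {
    return(tibble(strand = character(), start = integer(), end = integer(),
                  peak_count = double()))
  }
  grp <- cumsum(c(1L, diff(called) > merge_gap))
  purrr::map_dfr(split(called, grp), function(idx) {
    tibble(
      strand = strand,
      start = idx[[1]] - 1L,
      end = idx[[length(idx)]], # half-open
      peak_count = max(smoothed[idx])
    )
  })
}

# Centred moving sum with zero-padded edges; width is forced odd by using
# floor(window/2) on each side.
moving_sum <- function(x, window) {
  half <- window %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half - 1L, 0L)
  hi <- pmin(seq_len(n) + half, n)
  cs[hi + 1L] - cs[lo + 1L]
}

#' Bundle the full vsiRNA signature profile
#'
#' Computes every signature statistic from one set of mapping records:
#' size-by-strand counts (both weightings), 5' composition at the analysis
#' length (both weightings), A/U biases, the positional 5'-start profile,
#' strand balance, and hotspot calls on both strands.
#'
#' @param mappings Mapping tibble from [map_exact()].
#' @param genome_length Genome length in nt.
#' @param length Analysis length for the 5'-composition panels (default 21).
#' @param window,quantile,merge_gap Hotspot-caller knobs, see
#'   [detect_hotspots()].
#' @return A `vsirna_profile` object.
#' @export
vsirna_profile <- function(mappings, genome_length, length = 21L,
                           window = 21L, quantile = 0.99, merge_gap = 10L) {
  positional <- positional_profile(mappings, genome_length)
  comp_unique <- five_prime_composition(mappings, length, "unique")
  comp_total <- five_prime_composition(mappings, length, "total")
  structure(
    list(
      genome_length = as.integer(genome_length),
      analysis_length = as.integer(length),
      size_strand = size_strand_distribution(mappings),
      five_prime_unique = comp_unique,
      five_prime_total = comp_total,
      au_bias_unique = au_bias(comp_unique),
      au_bias_total = au_bias(comp_total),
      positional = positional,
      strand_fraction_sense = strand_fraction(mappings),
      hotspots = bind_rows(
        detect_hotspots(positional, "sense", window, quantile, merge_gap),
        detect_hotspots(positional, "antisense", window, quantile, merge_gap)
      )
    ),
    class = "vsirna_profile"
  )
}

#' @export
print.vsirna_profile <- function(x, ...) {
  tot <- sum(x$size_strand$total_count)
  uni <- sum(x$size_strand$unique_count)
  cat(sprintf(
    paste0(
      "<vsirna_profile> %d total / %d unique mapped records on a %d-nt genome\n",
      "  sense fraction %.3f; %d-nt 5' A/U bias %.3f (unique) / %.3f (total); ",
      "%d hotspot(s)\n"
    ),
    tot, uni, x$genome_length, x$strand_fraction_sense, x$analysis_length,
    x$au_bias_unique, x$au_bias_total, nrow(x$hotspots)
  ))
  invisible(x)
}

#' Tidy a vsiRNA profile
#'
#' @param x A `vsirna_profile`.
#' @param type Which component to return: size-by-strand counts, 5'
#'   composition (both weightings, long form), the positional profile, or
#'   hotspot calls.
#' @param ... Unused.
#' @return A tibble of the requested component.
#' @method tidy vsirna_profile
#' @export
tidy.vsirna_profile <- function(x, type = c("size_strand", "five_prime",
                                            "positional", "hotspots"), ...) {
  type <- match.arg(type)
  switch(type,
    size_strand = x$size_strand,
    five_prime = bind_rows(
      mutate(x$five_prime_unique, weighting = "unique"),
      mutate(x$five_prime_total, weighting = "total")
    ),
    positional = x$positional,
    hotspots = x$hotspots
  )
}

#' One-row summary of a vsiRNA profile
#'
#' @param x A `vsirna_profile`.
#' @param ... Unused.
#' @return A one-row tibble: total/unique record tallies, modal length and
#'   its total-weight fraction, sense fraction, A/U biases, hotspot count.
#' @method glance vsirna_profile
#' @export
glance.vsirna_profile <- function(x, ...) {
  by_len <- x$size_strand |>
    group_by(.data$length) |>
    summarise(total = sum(.data$total_count), .groups = "drop")
  tot <- sum(by_len$total)
  peak <- if (tot > 0) by_len$length[[which.max(by_len$total)]] else NA_integer_
  tibble(
    n_total = tot,
    n_unique = sum(x$size_strand$unique_count),
    peak_length = peak,
    peak_length_fraction = if (tot > 0) max(by_len$total) / tot else NA_real_,
    strand_fraction_sense = x$strand_fraction_sense,
    au_bias_unique = x$au_bias_unique,
    au_bias_total = x$au_bias_total,
    n_hotspots = nrow(x$hotspots)
  )
}

#' Write the profile components as TSV reports
#'
#' Emits `size_strand.tsv`, `five_prime_unique.tsv`, `five_prime_total.tsv`,
#' `positional.tsv` (1-based offsets, antisense counts negative, mirror-plot
#' convention) and `hotspots.tsv` (1-based inclusive intervals) into `dir`.
#'
#' @param profile A `vsirna_profile`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
profile_reports <- function(profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_report_tsv(profile$size_strand, file.path(dir, "size_strand.tsv"))
  write_report_tsv(profile$five_prime_unique, file.path(dir, "five_prime_unique.tsv"))
  write_report_tsv(profile$five_prime_total, file.path(dir, "five_prime_total.tsv"))
  profile$positional |>
    mutate(offset_1based = .data$offset + 1L,
           sense_count = .data$sense,
           antisense_count_negative = -.data$antisense) |>
    select("offset_1based", "sense_count", "antisense_count_negative") |>
    write_report_tsv(file.path(dir, "positional.tsv"))
  profile$hotspots |>
    mutate(start_1based = .data$start + 1L, end_1based = .data$end) |>
    select("strand", "start_1based", "end_1based", "peak_count") |>
    write_report_tsv(file.path(dir, "hotspots.tsv"))
  invisible(dir)
}
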