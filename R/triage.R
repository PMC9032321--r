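# Candidate-virus contig triage: an E-value/length screen against a viral
# reference search, followed by reclassification of each surviving contig by
# its best hit in a comprehensive (NT/NR-style) search carrying a
# viral/cellular subject category. Both screening thresholds are inclusive
# (evalue <= cutoff, length >= minimum).

#' Triage configuration
#'
#' @param evalue_max Maximum E-value for a viral-reference hit to count
#'   (inclusive). Default `1e-20`.
#' @param min_contig_length Minimum contig length in nt (inclusive).
#'   Default 3000.
#' @return A named list of validated thresholds.
#' @export
triage_config <- function(evalue_max = 1e-20, min_contig_length = 3000L) {
  stopifnot(is.numeric(evalue_max), evalue_max > 0,
            is.numeric(min_contig_length), min_contig_length >= 1)
  list(evalue_max = evalue_max, min_contig_length = as.integer(min_contig_length))
}

#' Screen contigs for candidate viral origin
#'
#' Keeps contigs having at least one viral-reference hit with
#' `evalue <= evalue_max` and contig length `>= min_contig_length`.
#' Output order follows the input contig order.
#'
#' @param contigs Sequence tibble (see [read_fasta()]).
#' @param viral_hits Hits tibble from a search against a viral reference set.
#' @param config A [triage_config()].
#' @return Character vector of retained contig ids.
#' @export
screen_candidates <- function(contigs, viral_hits, config = triage_config()) {
  orphan <- setdiff(unique(viral_hits$query_id), contigs$id)
  if (length(orphan)) {
    abort(sprintf(
      "viral hits reference unknown contig id(s): %s",
      paste(orphan, collapse = ", ")
    ))
  }
  good_hit <- viral_hits |>
    filter(.data$evalue <= config$evalue_max) |>
    pull("query_id") |>
    unique()
  contigs |>
    filter(nchar(.data$residues) >= config$min_contig_length,
           .data$id %in% good_hit) |>
    pull("id")
}

# Order hits by the best-hit precedence: bitscore desc, then evalue asc,
# then subject_id lexicographic.
best_hit_order <- function(hits) {
  order(-hits$bitscore, hits$evalue, hits$subject_id)
}

#' Classify screened contigs by their best comprehensive-search hit
#'
#' The best hit is the one with maximal bitscore (ties broken by smaller
#' E-value, then lexicographic subject id). A contig is labelled `viral` if
#' that hit's category is viral, `host_derived` if cellular, and `unresolved`
#' if it has no hits or the best hit's category is unknown. The `margin`
#' column reports the bitscore difference between the best viral and best
#' cellular hit (positive = viral stronger; `NA` when a side is absent), to
#' flag near-ties between insect and virus proteins.
#'
#' @param contig_ids Character vector of screened contig ids.
#' @param all_hits Hits tibble from the comprehensive search, with
#'   `subject_category` populated.
#' @return A verdict tibble with one row per contig: `contig_id`,
#'   `passed_screen`, `label`, best-hit fields (`best_subject_id`,
#'   `best_bitscore`, `best_evalue`, `best_category`) and `margin`.
#' @export
classify_contigs <- function(contig_ids, all_hits) {
  if (length(contig_ids) == 0L) {
    return(tibble(
      contig_id = character(), passed_screen = logical(), label = character(),
      best_subject_id = character(), best_bitscore = double(),
      best_evalue = double(), best_category = character(), margin = double()
    ))
  }
  purrr::map_dfr(contig_ids, function(cid) {
    h <- all_hits[all_hits$query_id == cid, , drop = FALSE]
    if (nrow(h) == 0L) {
      return(tibble(
        contig_id = cid, passed_screen = TRUE, label = "unresolved",
        best_subject_id = NA_character_, best_bitscore = NA_real_,
        best_evalue = NA_real_, best_category = NA_character_,
        margin = NA_real_
      ))
    }
    best <- h[best_hit_order(h)[1], ]
    label <- switch(best$subject_category,
      viral = "viral", cellular = "host_derived", "unresolved"
    )
    bv <- suppressWarnings(max(h$bitscore[h$subject_category == "viral"]))
    bc <- suppressWarnings(max(h$bitscore[h$subject_category == "cellular"]))
    tibble(
      contig_id = cid, passed_screen = TRUE, label = label,
      best_subject_id = best$subject_id, best_bitscore = best$bitscore,
      best_evalue = best$evalue, best_category = best$subject_category,
      margin = if (is.finite(bv) && is.finite(bc)) bv - bc else NA_real_
    )
  })
}

#' Classify a single contig
#'
#' Scalar convenience wrapper around [classify_contigs()].
#'
#' @param contig_id One contig id.
#' @param all_hits Comprehensive-search hits tibble.
#' @return A one-row verdict tibble.
#' @export
classify_contig <- function(contig_id, all_hits) {
  stopifnot(length(contig_id) == 1L)
  classify_contigs(contig_id, all_hits)
}

#' Summarise triage verdicts
#'
#' @param verdicts Verdict tibble from [classify_contigs()].
#' @return A one-row tibble: `candidates`, `host_derived`, `viral`,
#'   `unresolved`, `percent_host_derived` (100 * host / candidates, one
#'   decimal; `NA` for an empty verdict set).
#' @export
triage_summary <- function(verdicts) {
  n <- nrow(verdicts)
  host <- sum(verdicts$label == "host_derived")
  tibble(
    candidates = n,
    host_derived = host,
    viral = sum(verdicts$label == "viral"),
    unresolved = sum(verdicts$label == "unresolved"),
    percent_host_derived = if (n == 0L) NA_real_ else round(100 * host / n, 1)
  )
}

#' Run the full triage stage
#'
#' Screens contigs against the viral-reference hits, classifies the survivors
#' with the comprehensive-search hits, and summarises.
#'
#' @inheritParams screen_candidates
#' @param all_hits Comprehensive-search hits tibble.
#' @return A list with `verdicts` (per-contig tibble, screened-out contigs
#'   included with `passed_screen = FALSE` and label `unresolved`) and
#'   `summary` (one-row tibble over the screened candidates).
#' @export
triage_contigs <- function(contigs, viral_hits, all_hits,
                           config = triage_config()) {
  kept <- screen_candidates(contigs, viral_hits, config)
  verdicts <- classify_contigs(kept, all_hits)
  dropped <- setdiff(contigs$id, kept)
  if (length(dropped)) {
    verdicts <- bind_rows(verdicts, tibble(
      contig_id = dropped, passed_screen = FALSE, label = "unresolved",
      best_subject_id = NA_character_, best_bitscore = NA_real_,
      best_evalue = NA_real_, best_category = NA_character_, margin = NA_real_
    ))
    verdicts <- verdicts[match(contigs$id, verdicts$contig_id), ]
  }
  list(verdicts = as_tibble(verdicts),
       summary = triage_summary(verdicts[verdicts$passed_screen, ]))
}
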