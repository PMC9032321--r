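# Synthetic-data generators with known ground truth: viral genomes with
# planted ORF layouts (single long ORF flanked by short UTRs, or multi-ORF
# layouts with overlapping pairs), small-RNA libraries with controlled size,
# strand, 5'-base and hotspot structure, and contig-triage fixtures. All
# generators are bit-reproducible given their spec and seed; randomness is
# drawn from one local RNG stream seeded from the spec, leaving the caller's
# RNG untouched.

dna_bases <- c("A", "C", "G", "T")

non_stop_codons <- local({
  all <- names(codon_table)
  all[!(all %in% stop_codons)]
})

# Default size distribution over 18-30 nt: a dominant 21-nt class with the
# remaining mass spread evenly, mirroring the dicing-product peak the
# profiler is meant to detect.
default_size_probs <- function(peak21 = 0.60) {
  p <- setNames(rep((1 - peak21) / 12, 13), as.character(18:30))
  p[["21"]] <- peak21
  p
}

#' Specification for a synthetic small-RNA library
#'
#' @param n_reads Number of reads to generate.
#' @param size_probs Named probability vector over read lengths 18-30
#'   (names are lengths). Default: 0.60 at 21 nt, remainder uniform.
#' @param strand_prob_sense Probability that a viral read comes from the
#'   sense strand.
#' @param five_prime_probs Named probability vector over `c(A, C, G, U)`
#'   applied to the 5' base of 21-nt viral reads (other lengths follow
#'   genome composition). Default U 0.40 / A 0.35 / C 0.15 / G 0.10, the
#'   canonical A/U-biased signature.
#' @param hotspot_spec Tibble with columns `strand` (`sense`/`antisense`),
#'   `start`, `end` (0-based half-open 5'-position interval) and
#'   `multiplier` (sampling-rate multiplier), or `NULL` for a uniform
#'   positional distribution.
#' @param host_fraction Fraction of reads drawn as host background (random
#'   sequences verified not to match the genome on either strand).
#' @param seed RNG seed for this generator call.
#' @return A validated spec list.
#' @export
library_spec <- function(n_reads = 10000L,
                         size_probs = default_size_probs(),
                         strand_prob_sense = 0.5,
                         five_prime_probs = c(A = 0.35, C = 0.15, G = 0.10, U = 0.40),
                         hotspot_spec = NULL,
                         host_fraction = 0,
                         seed = 1L) {
  stopifnot(
    n_reads >= 1,
    abs(sum(size_probs) - 1) < 1e-9,
    identical(sort(names(size_probs)), sort(as.character(18:30))),
    strand_prob_sense >= 0, strand_prob_sense <= 1,
    abs(sum(five_prime_probs) - 1) < 1e-9,
    setequal(names(five_prime_probs), c("A", "C", "G", "U")),
    host_fraction >= 0, host_fraction <= 1
  )
  if (!is.null(hotspot_spec)) {
    stopifnot(all(c("strand", "start", "end", "multiplier") %in% names(hotspot_spec)))
  }
  list(
    n_reads = as.integer(n_reads), size_probs = size_probs,
    strand_prob_sense = strand_prob_sense, five_prime_probs = five_prime_probs,
    hotspot_spec = hotspot_spec, host_fraction = host_fraction,
    seed = as.integer(seed)
  )
}

#' Specification for a synthetic viral genome
#'
#' @param length Genome length in nt.
#' @param gc GC content (probability of G or C per background base).
#' @param orf_layout Tibble with columns `start`, `end` (0-based half-open,
#'   `end - start` divisible by 3) and optionally `strand` (only `"+"` is
#'   supported for planting) giving the ORFs to plant. Each planted span is
#'   ATG-initiated, stop-terminated and free of internal in-frame stops.
#' @param seed RNG seed.
#' @return A validated spec list.
#' @export
genome_spec <- function(length, gc = 0.5, orf_layout, seed = 1L) {
  orf_layout <- as_tibble(orf_layout)
  if (!"strand" %in% names(orf_layout)) orf_layout$strand <- "+"
  stopifnot(
    length >= 6, gc > 0, gc < 1,
    all(orf_layout$start >= 0), all(orf_layout$end <= length),
    all(orf_layout$end - orf_layout$start >= 6)
  )
  if (any((orf_layout$end - orf_layout$start) %% 3 != 0)) {
    abort("each planted ORF span must be divisible by 3")
  }
  if (any(orf_layout$strand != "+")) {
    abort("ORF planting is implemented for the '+' strand only")
  }
  orf_layout <- arrange(orf_layout, .data$start)
  # same-frame overlap forces one ORF's terminal stop inside the other
  n <- nrow(orf_layout)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ov <- min(orf_layout$end[[i]], orf_layout$end[[j]]) -
          max(orf_layout$start[[i]], orf_layout$start[[j]])
        same_frame <- (orf_layout$start[[i]] - orf_layout$start[[j]]) %% 3 == 0
        if (ov > 0 && same_frame) {
          abort("infeasible ORF layout: overlapping ORFs share a reading frame")
        }
      }
    }
  }
  list(length = as.integer(length), gc = gc, orf_layout = orf_layout,
       seed = as.integer(seed))
}

# Scan for constraint violations of the planted layout on a base vector `g`
# (character vector, 1 char per nt). Returns a list of violations, each
# list(kind, pos0) where pos0 is the 0-based offset of the offending codon.
planted_violations <- function(g, layout) {
  viol <- list()
  for (k in seq_len(nrow(layout))) {
    s <- layout$start[[k]]; e <- layout$end[[k]]
    starts0 <- seq(s, e - 3L, by = 3L)
    codons <- vapply(starts0, function(p) paste(g[(p + 1):(p + 3)], collapse = ""),
                     character(1))
    # internal stops (all but the terminal codon)
    bad <- which(codons[-length(codons)] %in% stop_codons)
    for (b in bad) viol[[length(viol) + 1L]] <- list(kind = "internal_stop",
                                                    pos0 = starts0[[b]], orf = k)
    # upstream in-frame ATG with no intervening stop would extend the
    # reported ORF past the planted start (longest-per-stop rule)
    p <- s - 3L
    while (p >= 0L) {
      cod <- paste(g[(p + 1):(p + 3)], collapse = "")
      if (cod %in% stop_codons) break
      if (cod == "ATG") {
        viol[[length(viol) + 1L]] <- list(kind = "upstream_atg", pos0 = p, orf = k)
        break
      }
      p <- p - 3L
    }
  }
  viol
}

#' Generate a synthetic viral genome with planted ORFs
#'
#' Background bases are i.i.d. with the requested GC content; each planted
#' ORF gets an ATG start, a stop terminus, stop-free interior codons and a
#' clean upstream frame (so ORF prediction recovers exactly the planted
#' coordinates). Spurious ATG-initiated spans of `min_spurious_aa` or more
#' amino acids arising by chance outside the layout are disrupted by
#' inserting stops.
#'
#' @param spec A [genome_spec()].
#' @param genome_id Id for the generated record.
#' @param min_spurious_aa Minimum protein length (aa) at which an unplanned
#'   ORF is considered spurious and disrupted.
#' @return List with `genome` (one-row sequence tibble), `orfs` (planted
#'   truth tibble as [find_orfs()] would report it) and `annotation`
#'   (ground-truth [segment_genome()] object).
#' @export
generate_genome <- function(spec, genome_id = "synthetic_genome",
                            min_spurious_aa = 100L) {
  withr::with_seed(spec$seed, generate_genome_impl(spec, genome_id, min_spurious_aa))
}

generate_genome_impl <- function(spec, genome_id, min_spurious_aa) {
  L <- spec$length
  layout <- spec$orf_layout
  probs <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2, (1 - spec$gc) / 2)
  for (attempt in 1:10) {
    g <- sample(dna_bases, L, replace = TRUE, prob = probs)
    fixed <- logical(L) # 1-based mask of immovable positions
    for (k in seq_len(nrow(layout))) {
      s <- layout$start[[k]]; e <- layout$end[[k]]
      g[(s + 1):(s + 3)] <- c("A", "T", "G")
      g[(e - 2):e] <- strsplit(sample(stop_codons, 1), "")[[1]]
      fixed[(s + 1):(s + 3)] <- TRUE
      fixed[(e - 2):e] <- TRUE
      # interior codons drawn stop-free up front
      if (e - s > 6L) {
        interior <- seq(s + 3L, e - 6L, by = 3L)
        free_interior <- interior[!vapply(interior, function(p)
          any(fixed[(p + 1):(p + 3)]), logical(1))]
        if (length(free_interior)) {
          cods <- sample(non_stop_codons, length(free_interior), replace = TRUE)
          for (ii in seq_along(free_interior)) {
            p <- free_interior[[ii]]
            g[(p + 1):(p + 3)] <- strsplit(cods[[ii]], "")[[1]]
          }
        }
      }
    }
    in_layout <- logical(L)
    for (k in seq_len(nrow(layout))) {
      in_layout[(layout$start[[k]] + 1):layout$end[[k]]] <- TRUE
    }
    # guard stop immediately upstream of each planted start where the
    # triplet is free and outside every planted span
    for (k in seq_len(nrow(layout))) {
      s <- layout$start[[k]]
      if (s >= 3L) {
        idx <- (s - 2):s # 1-based positions of codon [s-3, s)
        if (!any(fixed[idx]) && !any(in_layout[idx])) {
          g[idx] <- strsplit(sample(stop_codons, 1), "")[[1]]
        }
      }
    }
    # randomized repair of residual violations (overlapping frames)
    ok <- FALSE
    for (sweep in 1:300) {
      viol <- planted_violations(g, layout)
      if (!length(viol)) { ok <- TRUE; break }
      v <- viol[[1]]
      idx <- (v$pos0 + 1):(v$pos0 + 3)
      free <- !fixed[idx]
      if (!any(free)) {
        ok <- FALSE
        break # immovable contradiction; regenerate
      }
      g[idx[free]] <- sample(dna_bases, sum(free), replace = TRUE)
    }
    if (!ok) next
    # disrupt spurious long (+)-strand ORFs outside the layout; exact
    # planted recovery is guaranteed for (+)-strand prediction, the
    # pipeline's default for positive-sense RNA viruses
    planted_key <- paste(layout$start, layout$end, "+")
    spurious_remaining <- function() {
      found <- find_orfs(paste(g, collapse = ""),
                         min_protein_len = min_spurious_aa, strands = "+")
      found[!(paste(found$start, found$end, found$strand) %in% planted_key), ,
            drop = FALSE]
    }
    ok_spur <- TRUE
    for (sweep in 1:50) {
      spurious <- spurious_remaining()
      if (nrow(spurious) == 0L) break
      sp <- spurious[1, ]
      cod_starts <- seq(sp$start + 3L, sp$end - 6L, by = 3L)
      usable <- cod_starts[vapply(cod_starts, function(p) {
        idx <- (p + 1):(p + 3)
        !any(fixed[idx]) && !any(in_layout[idx])
      }, logical(1))]
      if (!length(usable)) { ok_spur <- FALSE; break }
      p <- usable[[ceiling(length(usable) / 2)]]
      g[(p + 1):(p + 3)] <- strsplit(sample(stop_codons, 1), "")[[1]]
    }
    if (!ok_spur || nrow(spurious_remaining()) > 0L) next
    if (length(planted_violations(g, layout))) next
    residues <- paste(g, collapse = "")
    orfs <- tibble(
      start = layout$start, end = layout$end, strand = "+",
      frame = layout$start %% 3L,
      protein = vapply(seq_len(nrow(layout)), function(k)
        translate(substr(residues, layout$start[[k]] + 1L, layout$end[[k]])),
        character(1))
    )
    genome <- tibble(id = genome_id, description = "synthetic viral genome",
                     residues = residues)
    return(list(
      genome = genome,
      orfs = orfs,
      annotation = segment_genome(L, orfs, genome_id)
    ))
  }
  abort("infeasible ORF layout: could not satisfy planted constraints after 10 attempts")
}

# Per-strand 5'-position sampling weights of a given read length:
# uniform over feasible positions, multiplied inside hotspot intervals.
position_weights <- function(L, len, strand, hotspot_spec) {
  w <- numeric(L) # index = 0-based five_prime offset + 1
  if (strand == "sense") {
    w[1:(L - len + 1)] <- 1
  } else {
    w[len:L] <- 1
  }
  if (!is.null(hotspot_spec)) {
    hs <- hotspot_spec[hotspot_spec$strand == strand, , drop = FALSE]
    for (k in seq_len(nrow(hs))) {
      idx <- (hs$start[[k]] + 1):hs$end[[k]]
      w[idx] <- w[idx] * hs$multiplier[[k]]
    }
  }
  w
}

#' Generate a synthetic small-RNA library from a viral genome
#'
#' Viral reads are exact substrings (sense) or reverse complements of
#' substrings (antisense) of the genome, with 5' positions drawn uniformly
#' except inside hotspot intervals, lengths from `size_probs` and strand
#' from `strand_prob_sense`. For 21-nt reads the 5'-base law
#' `five_prime_probs` is imposed exactly by stratifying candidate 5'
#' positions by the base they would yield and sampling strata at the target
#' frequencies. Host-background reads are i.i.d. random sequences verified
#' not to match the genome on either strand.
#'
#' @param genome One-row sequence tibble or DNA string (N-free).
#' @param spec A [library_spec()].
#' @return List with `reads` (FASTQ-ready tibble: `id`, `residues`,
#'   `quality`) and `truth` (per-read tibble: `id`, `origin`, `strand`,
#'   `five_prime_pos`, `length`).
#' @export
generate_library <- function(genome, spec) {
  withr::with_seed(spec$seed, generate_library_impl(genome, spec))
}

generate_library_impl <- function(genome, spec) {
  g <- as_genome(genome)
  L <- nchar(g$residues)
  max_len <- max(as.integer(names(spec$size_probs)[spec$size_probs > 0]))
  if (L <= max_len) abort("genome must be longer than the maximum read length")
  if (stringr::str_detect(g$residues, "N")) {
    abort("generate_library requires an N-free genome")
  }
  n_host <- round(spec$n_reads * spec$host_fraction)
  n_viral <- spec$n_reads - n_host
  gbase <- strsplit(g$residues, "")[[1]]

  viral <- NULL
  if (n_viral > 0L) {
    lens <- as.integer(sample(names(spec$size_probs), n_viral, replace = TRUE,
                              prob = spec$size_probs))
    strands <- ifelse(runif(n_viral) < spec$strand_prob_sense, "sense", "antisense")
    fp <- integer(n_viral)
    # 5' base a read would get if its 5' position were offset p (0-based):
    # the genome base itself (sense) or its complement (antisense)
    base_sense <- gbase
    base_anti <- chartr("ACGT", "TGCA", gbase)
    dna_probs <- spec$five_prime_probs[c("A", "C", "G", "U")]
    names(dna_probs) <- c("A", "C", "G", "T")
    for (strand in c("sense", "antisense")) {
      for (len in unique(lens)) {
        sel <- which(lens == len & strands == strand)
        if (!length(sel)) next
        w <- position_weights(L, len, strand, spec$hotspot_spec)
        if (len == 21L) {
          pos_base <- if (strand == "sense") base_sense else base_anti
          draw_base <- sample(names(dna_probs), length(sel), replace = TRUE,
                              prob = dna_probs)
          for (b in unique(draw_base)) {
            sb <- sel[draw_base == b]
            wb <- w * (pos_base == b)
            if (!any(wb > 0)) {
              abort(sprintf(
                "no feasible 5' position with base %s for 21-nt %s reads; use a longer genome",
                chartr("T", "U", b), strand
              ))
            }
            fp[sb] <- sample.int(L, length(sb), replace = TRUE, prob = wb) - 1L
          }
        } else {
          fp[sel] <- sample.int(L, length(sel), replace = TRUE, prob = w) - 1L
        }
      }
    }
    left <- ifelse(strands == "sense", fp, fp - lens + 1L)
    seqs <- substring(g$residues, left + 1L, left + lens)
    anti <- strands == "antisense"
    seqs[anti] <- revcomp(seqs[anti])
    viral <- tibble(
      residues = seqs, origin = "viral", strand = strands,
      five_prime_pos = fp, length = lens
    )
  }

  host <- NULL
  if (n_host > 0L) {
    idx <- build_index(g$residues, min_len = 18L,
                       max_len = max_len)
    lens <- as.integer(sample(names(spec$size_probs), n_host, replace = TRUE,
                              prob = spec$size_probs))
    seqs <- vapply(lens, function(n)
      paste(sample(dna_bases, n, replace = TRUE), collapse = ""), character(1))
    for (i in seq_len(n_host)) {
      while (length(index_occurrences(idx, seqs[[i]])) ||
             length(index_occurrences(idx, revcomp(seqs[[i]])))) {
        seqs[[i]] <- paste(sample(dna_bases, lens[[i]], replace = TRUE),
                           collapse = "")
      }
    }
    host <- tibble(
      residues = seqs, origin = "host", strand = NA_character_,
      five_prime_pos = NA_integer_, length = lens
    )
  }

  truth <- bind_rows(viral, host)
  truth$id <- sprintf("r%07d", seq_len(nrow(truth)))
  reads <- tibble(
    id = truth$id, residues = truth$residues,
    quality = strrep("I", truth$length)
  )
  list(reads = reads,
       truth = select(truth, "id", "origin", "strand", "five_prime_pos", "length"))
}

#' Generate a contig-triage fixture with planted labels
#'
#' Every candidate contig is at least 3000 nt and carries a viral-reference
#' hit at `evalue <= 1e-20`, so all pass the screen; exactly `n_viral`
#' contigs get a comprehensive-search best hit of category `viral`, the rest
#' a stronger `cellular` best hit (host-derived).
#'
#' @param n_candidates Number of candidate contigs.
#' @param n_viral Number of truly viral contigs (`<= n_candidates`).
#' @param seed RNG seed.
#' @return List with `contigs` (sequence tibble), `viral_hits` and
#'   `all_hits` (hit tibbles) and `truth` (`contig_id`, `label`).
#' @export
generate_triage_fixture <- function(n_candidates, n_viral, seed = 1L) {
  stopifnot(n_viral <= n_candidates)
  withr::with_seed(seed, {
    ids <- sprintf("contig_%04d", seq_len(n_candidates))
    lens <- sample(3000:6000, n_candidates, replace = TRUE)
    residues <- vapply(lens, function(n)
      paste(sample(dna_bases, n, replace = TRUE), collapse = ""), character(1))
    contigs <- tibble(id = ids, description = "synthetic contig",
                      residues = residues)
    viral_idx <- sort(sample.int(n_candidates, n_viral))
    is_viral <- seq_len(n_candidates) %in% viral_idx

    mk_hit <- function(qid, sid, bitscore, category, qlen) {
      alen <- pmin(qlen %/% 3L, as.integer(100 + round(bitscore)))
      tibble(
        query_id = qid, subject_id = sid,
        percent_identity = round(runif(length(qid), 30, 95), 1),
        aln_length = alen,
        mismatches = as.integer(round(alen * 0.2)),
        gap_opens = 1L,
        q_start = 1L, q_end = pmin(qlen, alen * 3L),
        s_start = 1L, s_end = alen,
        evalue = 10^-(pmin(bitscore / 2, 180)),
        bitscore = round(bitscore, 1),
        subject_category = category
      )
    }

    ref_bits <- runif(n_candidates, 80, 300)
    viral_hits <- mk_hit(ids, sprintf("viral_ref_%03d", sample.int(500, n_candidates,
                                                                   replace = TRUE)),
                         pmax(ref_bits, 45), "viral", lens) |>
      mutate(evalue = 10^-runif(n_candidates, 21, 60)) # all pass the screen

    best_bits <- runif(n_candidates, 300, 900)
    weaker_bits <- best_bits - runif(n_candidates, 50, 200)
    all_hits <- bind_rows(
      mk_hit(ids, ifelse(is_viral, sprintf("virus_prot_%04d", seq_len(n_candidates)),
                         sprintf("insect_prot_%04d", seq_len(n_candidates))),
             best_bits, ifelse(is_viral, "viral", "cellular"), lens),
      mk_hit(ids, ifelse(is_viral, sprintf("insect_prot_x%04d", seq_len(n_candidates)),
                         sprintf("virus_prot_x%04d", seq_len(n_candidates))),
             weaker_bits, ifelse(is_viral, "cellular", "viral"), lens)
    )
    truth <- tibble(contig_id = ids,
                    label = ifelse(is_viral, "viral", "host_derived"))
    list(contigs = contigs, viral_hits = viral_hits, all_hits = all_hits,
         truth = truth)
  })
}
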