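mk_mapping <- function(residues, count, strand, five_prime_pos = 0L,
                       left = NULL) {
  n <- nchar(residues)
  tibble::tibble(
    residues = residues, count = as.integer(count), genome_id = "g",
    left = left %||% ifelse(strand == "sense", five_prime_pos,
                            five_prime_pos - n + 1L),
    strand = strand, five_prime_pos = as.integer(five_prime_pos)
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("size_strand_distribution separates the two weightings", {
  m <- dplyr::bind_rows(
    mk_mapping(strrep("A", 21), 5, "sense", 30L),
    mk_mapping(strrep("C", 21), 1, "sense", 60L),
    mk_mapping(strrep("G", 21), 1, "sense", 90L),
    mk_mapping(strrep("T", 21), 7, "antisense", 120L)
  )
  d <- size_strand_distribution(m)
  at21 <- d[d$length == 21L, ]
  expect_equal(at21$total_count[at21$strand == "sense"], 7L)
  expect_equal(at21$total_count[at21$strand == "antisense"], 7L)
  expect_equal(at21$unique_count[at21$strand == "sense"], 3L)
  expect_equal(at21$unique_count[at21$strand == "antisense"], 1L)
  # missing lengths are explicit zeros; unique <= total elementwise
  expect_equal(nrow(d), 26L)
  expect_true(all(d$unique_count <= d$total_count))
  expect_equal(sum(d$total_count), sum(m$count))

  empty <- size_strand_distribution(m[0, ])
  expect_true(all(empty$total_count == 0L))
})

test_that("five_prime_composition reports RNA bases in both weightings", {
  m <- dplyr::bind_rows(
    mk_mapping(paste0("T", strrep("A", 20)), 1, "sense", 0L),
    mk_mapping(paste0("T", strrep("C", 20)), 1, "sense", 40L),
    mk_mapping(paste0("A", strrep("C", 20)), 1, "sense", 80L),
    mk_mapping(paste0("G", strrep("C", 20)), 1, "sense", 120L)
  )
  comp <- five_prime_composition(m, 21L, "unique")
  expect_equal(comp$fraction[comp$base == "U"], 0.5)
  expect_equal(comp$fraction[comp$base == "A"], 0.25)
  expect_equal(comp$fraction[comp$base == "G"], 0.25)
  expect_equal(comp$fraction[comp$base == "C"], 0)
  expect_equal(sum(comp$fraction), 1, tolerance = 1e-9)

  # total weighting diverges when one read dominates
  m$count[[4]] <- 97L
  tot <- five_prime_composition(m, 21L, "total")
  expect_equal(which.max(tot$fraction), which(tot$base == "G"))

  # no records of the length -> all-NA
  none <- five_prime_composition(m, 25L)
  expect_true(all(is.na(none$fraction)))
})

test_that("au_bias sums the A and U fractions", {
  comp <- tibble::tibble(base = c("A", "C", "G", "U"),
                         fraction = c(0.35, 0.15, 0.10, 0.40))
  expect_equal(au_bias(comp), 0.75)
  uniform <- tibble::tibble(base = c("A", "C", "G", "U"), fraction = 0.25)
  expect_equal(au_bias(uniform), 0.5)
  expect_true(is.na(au_bias(tibble::tibble(base = c("A", "C", "G", "U"),
                                           fraction = NA_real_))))
})

test_that("positional_profile accumulates 5'-start weights per strand", {
  m <- mk_mapping(strrep("A", 21), 4, "sense", 10L)
  prof <- positional_profile(m, 100L)
  expect_equal(prof$sense[[11]], 4)
  expect_equal(sum(prof$sense), 4)
  expect_equal(sum(prof$antisense), 0)

  bad <- mk_mapping(strrep("A", 21), 1, "sense", 200L)
  expect_error(positional_profile(bad, 100L), "outside")
})

test_that("profile outputs are permutation-invariant and conserve weight", {
  set.seed(55)
  gs <- genome_spec(2000, 0.5, tibble::tibble(start = 99, end = 1200), seed = 5)
  g <- generate_genome(gs)$genome
  lib <- generate_library(g, library_spec(n_reads = 4000, seed = 6))
  m <- map_exact(collapse_reads(lib$reads), build_index(g))
  perm <- m[sample(nrow(m)), ]
  expect_equal(size_strand_distribution(m), size_strand_distribution(perm))
  expect_equal(five_prime_composition(m, 21, "total"),
               five_prime_composition(perm, 21, "total"))
  prof <- positional_profile(m, 2000L)
  expect_equal(sum(prof$sense), sum(m$count[m$strand == "sense"]))
  expect_equal(sum(prof$antisense), sum(m$count[m$strand == "antisense"]))
  expect_equal(strand_fraction(m), strand_fraction(perm))
})

test_that("removing antisense records zeroes antisense outputs", {
  set.seed(66)
  gs <- genome_spec(1500, 0.5, tibble::tibble(start = 30, end = 900), seed = 7)
  g <- generate_genome(gs)$genome
  lib <- generate_library(g, library_spec(n_reads = 2000, seed = 8))
  m <- map_exact(collapse_reads(lib$reads), build_index(g))
  sense_only <- m[m$strand == "sense", ]
  d <- size_strand_distribution(sense_only)
  expect_true(all(d$total_count[d$strand == "antisense"] == 0L))
  expect_equal(strand_fraction(sense_only), 1)
  prof <- positional_profile(sense_only, 1500L)
  expect_true(all(prof$antisense == 0))
})

test_that("hotspot calling follows the quantile-and-merge definition", {
  # single spike on a zero background -> exactly one interval over the spike
  prof <- tibble::tibble(offset = 0:4999, sense = 0, antisense = 0)
  prof$sense[[2500]] <- 100
  hs <- detect_hotspots(prof, "sense")
  expect_equal(nrow(hs), 1L)
  expect_true(hs$start <= 2499 && hs$end >= 2500)
  expect_equal(hs$peak_count, 100)

  # all-zero profile -> empty
  empty <- detect_hotspots(prof, "antisense")
  expect_equal(nrow(empty), 0L)

  # flat nonzero profile -> degenerate near-empty output
  flat <- tibble::tibble(offset = 0:999, sense = 1, antisense = 0)
  hs_flat <- detect_hotspots(flat, "sense")
  expect_lte(sum(hs_flat$end - hs_flat$start), ceiling(0.01 * 1000) + 21)
})

test_that("planted hotspots are recovered on their own strands only", {
  set.seed(91)
  gs <- genome_spec(4000, 0.5, tibble::tibble(start = 60, end = 3600), seed = 12)
  g <- generate_genome(gs)$genome
  hs_spec <- tibble::tibble(
    strand = c("sense", "antisense"),
    start = c(800L, 2600L), end = c(1000L, 2800L), multiplier = 10
  )
  lib <- generate_library(g, library_spec(
    n_reads = 20000, hotspot_spec = hs_spec, seed = 13
  ))
  m <- map_exact(collapse_reads(lib$reads), build_index(g))
  prof <- positional_profile(m, 4000L)
  sense_calls <- detect_hotspots(prof, "sense")
  anti_calls <- detect_hotspots(prof, "antisense")
  overlaps_interval <- function(calls, lo, hi) {
    any(pmin(calls$end, hi) - pmax(calls$start, lo) > 0)
  }
  expect_true(overlaps_interval(sense_calls, 800, 1000))
  expect_true(overlaps_interval(anti_calls, 2600, 2800))
  expect_false(overlaps_interval(sense_calls, 2600, 2800))
  expect_false(overlaps_interval(anti_calls, 800, 1000))
})

test_that("the profile bundle satisfies its internal invariants", {
  set.seed(14)
  gs <- genome_spec(3000, 0.5, tibble::tibble(start = 150, end = 2400), seed = 15)
  g <- generate_genome(gs)$genome
  lib <- generate_library(g, library_spec(n_reads = 10000, seed = 16))
  m <- map_exact(collapse_reads(lib$reads), build_index(g))
  p <- vsirna_profile(m, 3000L)
  expect_s3_class(p, "vsirna_profile")
  expect_equal(sum(p$size_strand$total_count), sum(m$count))
  expect_equal(sum(p$size_strand$unique_count), nrow(m))
  expect_equal(sum(p$five_prime_unique$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(p$five_prime_total$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(p$positional$sense) + sum(p$positional$antisense),
               sum(m$count))
  expect_gte(p$strand_fraction_sense, 0)
  expect_lte(p$strand_fraction_sense, 1)

  gl <- glance(p)
  expect_equal(gl$peak_length, 21L)
  td <- tidy(p, "five_prime")
  expect_equal(nrow(td), 8L)
})

test_that("profiler estimates converge toward generator parameters with n", {
  gs <- genome_spec(3000, 0.5, tibble::tibble(start = 150, end = 2400), seed = 17)
  g <- generate_genome(gs)$genome
  est <- function(n, seed) {
    lib <- generate_library(g, library_spec(n_reads = n, seed = seed))
    m <- map_exact(collapse_reads(lib$reads), build_index(g))
    p <- vsirna_profile(m, 3000L)
    by_len <- dplyr::summarise(
      dplyr::group_by(p$size_strand, length),
      total = sum(total_count), .groups = "drop"
    )
    c(
      p21 = by_len$total[by_len$length == 21] / sum(by_len$total),
      sense = p$strand_fraction_sense,
      u = p$five_prime_total$fraction[p$five_prime_total$base == "U"],
      a = p$five_prime_total$fraction[p$five_prime_total$base == "A"]
    )
  }
  truth <- c(p21 = 0.60, sense = 0.50, u = 0.40, a = 0.35)
  err_small <- abs(est(5000, 18) - truth)
  err_big <- abs(est(50000, 19) - truth)
  expect_gte(sum(err_big < err_small), 3)
})

test_that("profile plots build without error", {
  set.seed(20)
  gs <- genome_spec(1500, 0.5, tibble::tibble(start = 30, end = 1230), seed = 21)
  g <- generate_genome(gs)$genome
  lib <- generate_library(g, library_spec(n_reads = 2000, seed = 22))
  m <- map_exact(collapse_reads(lib$reads), build_index(g))
  p <- vsirna_profile(m, 1500L)
  expect_s3_class(autoplot(p, "size"), "ggplot")
  expect_s3_class(autoplot(p, "positional"), "ggplot")
  expect_s3_class(autoplot(p, "five_prime"), "ggplot")
  ann <- segment_genome(1500, find_orfs(g, 100), "g")
  expect_s3_class(autoplot(ann), "ggplot")
})
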