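test_that("extract_by_length keeps the inclusive 18-30 nt window", {
  reads <- tibble::tibble(
    id = sprintf("r%d", 1:4),
    residues = vapply(c(17, 18, 30, 31), function(n) strrep("A", n), character(1)),
    quality = strrep("I", c(17, 18, 30, 31))
  )
  kept <- extract_by_length(reads)
  expect_equal(kept$id, c("r2", "r3"))
  # idempotent
  expect_equal(extract_by_length(kept), kept)
  expect_equal(nrow(extract_by_length(reads[0, ])), 0L)
})

test_that("collapse_reads counts multiplicities and drops N reads", {
  reads <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    residues = c("ACGT", "ACGT", "TTTT", "ACNT"),
    quality = "IIII"
  )
  expect_message(col <- collapse_reads(reads), "dropped 1 read")
  expect_equal(col$residues, c("ACGT", "TTTT"))
  expect_equal(col$count, c(2L, 1L))
  expect_equal(attr(col, "dropped_n"), 1L)
  expect_equal(sum(col$count), 3L) # conservation of N-free reads
})

test_that("collapse_reads conserves total counts on a large library", {
  set.seed(88)
  # draw from a small pool so duplicates are common
  pool <- vapply(1:200, function(i) random_dna(21), character(1))
  reads <- tibble::tibble(
    id = sprintf("r%05d", 1:10000),
    residues = sample(pool, 10000, replace = TRUE)
  )
  col <- collapse_reads(reads)
  expect_equal(sum(col$count), 10000L)
  # brute-force tally of one sequence
  probe <- pool[[7]]
  expect_equal(col$count[col$residues == probe],
               sum(reads$residues == probe))
  # sorted by descending count then lexicographic
  expect_true(all(diff(col$count) <= 0))
})

test_that("build_index answers its length range and rejects others", {
  g <- random_dna(30)
  idx <- build_index(g, 18, 30)
  hit <- map_exact(tibble::tibble(residues = g, count = 1L), idx)
  expect_equal(hit$left, 0L)
  expect_equal(hit$strand, "sense")

  expect_error(
    map_exact(tibble::tibble(residues = strrep("A", 17), count = 1L), idx),
    "outside the indexed range"
  )
  expect_error(build_index(random_dna(10), 18, 30), "shorter than min_len")
})

test_that("genome positions containing N never match", {
  g <- paste0(strrep("A", 20), "N", strrep("A", 20))
  idx <- build_index(g, 18, 30)
  m <- map_exact(tibble::tibble(residues = strrep("A", 21), count = 1L), idx)
  # only 20 consecutive As exist on either side of the N: every candidate
  # 21-nt span crosses the N, so nothing may match
  expect_equal(nrow(m), 0L)
})

test_that("map_exact places sense and antisense reads per the 5' convention", {
  idx <- build_index("GGGACGTACGTAGGG", 9, 9)
  sense <- map_exact(tibble::tibble(residues = "ACGTACGTA", count = 1L), idx)
  expect_equal(sense$strand, "sense")
  expect_equal(sense$left, 3L)
  expect_equal(sense$five_prime_pos, 3L)

  anti <- map_exact(tibble::tibble(residues = "TACGTACGT", count = 1L), idx)
  expect_equal(anti$strand, "antisense")
  expect_equal(anti$left, 3L)
  expect_equal(anti$five_prime_pos, 11L)
})

test_that("a single substitution yields zero records", {
  set.seed(11)
  g <- random_dna(400)
  idx <- build_index(g)
  sub <- substr(g, 101, 121)
  mutated <- sub
  old <- substr(mutated, 10, 10)
  substr(mutated, 10, 10) <- setdiff(c("A", "C", "G", "T"), old)[1]
  m <- map_exact(tibble::tibble(residues = mutated, count = 1L), idx)
  expect_true(all(m$residues != mutated) || nrow(m) == 0L)
  # the unmutated substring still maps at its origin
  m0 <- map_exact(tibble::tibble(residues = sub, count = 1L), idx)
  expect_true(100L %in% m0$left)
})

test_that("drawn genome substrings always map back to their origin", {
  set.seed(22)
  g <- random_dna(3000)
  idx <- build_index(g)
  for (rep in 1:50) {
    n <- sample(18:30, 1)
    left <- sample(0:(3000 - n), 1)
    q <- substr(g, left + 1, left + n)
    m <- map_exact(tibble::tibble(residues = q, count = 1L), idx)
    expect_true(any(m$left == left & m$strand == "sense"))
  }
})

test_that("mapping reverse-complemented reads mirrors strands", {
  set.seed(33)
  g <- random_dna(1500)
  idx <- build_index(g)
  reads <- tibble::tibble(
    residues = vapply(1:40, function(i) {
      n <- sample(18:30, 1)
      left <- sample(0:(1500 - n), 1)
      substr(g, left + 1, left + n)
    }, character(1)),
    count = 1L
  )
  fwd <- map_exact(reads, idx)
  rev <- map_exact(dplyr::mutate(reads, residues = revcomp(residues)), idx)
  flip <- rev |>
    dplyr::mutate(strand = ifelse(strand == "sense", "antisense", "sense"),
                  residues = revcomp(residues)) |>
    dplyr::mutate(five_prime_pos = ifelse(strand == "sense", left,
                                          left + nchar(residues) - 1L)) |>
    dplyr::arrange(left, strand, residues)
  expect_equal(
    as.data.frame(fwd[order(fwd$left, fwd$strand, fwd$residues),
                      c("left", "strand", "residues")]),
    as.data.frame(flip[, c("left", "strand", "residues")]),
    ignore_attr = TRUE
  )
})

test_that("index lookups match the naive substring-scan oracle", {
  set.seed(44)
  g <- random_dna(5000)
  idx <- build_index(g)
  queries <- tibble::tibble(
    residues = vapply(1:1000, function(i) {
      n <- sample(18:30, 1)
      if (runif(1) < 0.6) {
        left <- sample(0:(5000 - n), 1)
        s <- substr(g, left + 1, left + n)
        if (runif(1) < 0.5) s <- revcomp(s)
        s
      } else {
        random_dna(n)
      }
    }, character(1)),
    count = 1L
  ) |> dplyr::distinct(residues, .keep_all = TRUE)
  got <- map_exact(queries, idx)
  want <- naive_map(queries, g)
  expect_equal(as.data.frame(got), as.data.frame(want), ignore_attr = TRUE)
})

test_that("mapping_report writes 1-based coordinates", {
  idx <- build_index("GGGACGTACGTAGGG", 9, 9)
  m <- map_exact(tibble::tibble(residues = "ACGTACGTA", count = 3L), idx)
  p <- tempfile(fileext = ".tsv")
  mapping_report(m, p)
  rep <- utils::read.delim(p)
  expect_equal(rep$left_1based, 4L)
  expect_equal(rep$five_prime_pos_1based, 4L)
  expect_equal(rep$count, 3L)
})
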