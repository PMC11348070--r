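fwd <- "AGCGTCGAATACCACTAC"
rev <- "GACCACGAGCTCCATTAG"

test_that("FASTA/FASTQ parsing aggregates counts and flags malformed input", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1", strrep("AC", 15), ">r2", strrep("AG", 15)), fa)
  lib <- read_library(fa)
  expect_equal(nrow(lib), 2)
  expect_equal(lib$count, c(1, 1))

  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c(
    "@r1", strrep("AC", 15), "+", strrep("I", 30),
    "@r2", strrep("AC", 15), "+", strrep("I", 30)
  ), fq)
  lib <- read_library(fq)
  expect_equal(nrow(lib), 1)
  expect_equal(lib$count, 2)
  expect_equal(nrow(read_library(fq, aggregate = FALSE)), 2)

  bad <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", strrep("AC", 15), "+"), bad) # truncated record
  expect_error(read_library(bad), "[Mm]alformed|truncated")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_library(empty), "Empty")
  expect_error(read_library("no/such/file.fa"), "not found")
})

test_that("library round-trips through FASTA with sidecar counts", {
  lib <- generate_initial_library(20, counts_dist = "geometric", seed = 5)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_library(lib, fa, counts = "sidecar")
  back <- read_library(fa, counts_tsv = paste0(fa, ".counts.tsv"))
  expect_setequal(back$sequence, lib$sequence)
  merged <- dplyr::inner_join(back, tibble::as_tibble(lib), by = "sequence")
  expect_equal(merged$count.x, merged$count.y)

  fa2 <- withr::local_tempfile(fileext = ".fasta")
  write_library(lib, fa2, counts = "duplicate")
  back2 <- read_library(fa2)
  expect_equal(sum(back2$count), sum(lib$count))
})

test_that("extract_insert anchors the primers and reports rejection reasons", {
  ins <- strrep("AC", 15)
  res <- extract_insert(paste0(fwd, ins, rev))
  expect_equal(res$insert, ins)
  expect_equal(res$status, "ok")

  # one mismatch in the forward primer is tolerated at max_mismatch = 1
  fwd_mm <- paste0("T", substr(fwd, 2, 18))
  expect_equal(extract_insert(paste0(fwd_mm, ins, rev))$insert, ins)
  expect_equal(
    extract_insert(paste0(fwd_mm, ins, rev), max_mismatch = 0)$reason,
    "not_found"
  )

  short <- extract_insert(paste0(fwd, strrep("A", 29), rev))
  expect_equal(short$status, "rejected")
  expect_equal(short$reason, "bad_length")

  amb <- extract_insert(paste0(fwd, paste0(strrep("A", 29), "N"), rev))
  expect_equal(amb$reason, "ambiguous_base")

  expect_equal(extract_insert(strrep("A", 66))$reason, "not_found")
  expect_error(extract_insert("XYZ"), "A, C, G, T, N")
})

test_that("extract_insert recovers inserts from either read orientation", {
  revcomp_chr <- function(x) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }
  set.seed(42)
  inserts <- replicate(1000, paste(sample(c("A", "C", "G", "T"), 30,
                                          replace = TRUE), collapse = ""))
  reads <- paste0(fwd, inserts, rev)
  flip <- seq_along(reads) %% 2 == 0
  reads[flip] <- vapply(reads[flip], revcomp_chr, character(1), USE.NAMES = FALSE)
  res <- extract_insert(reads)
  expect_true(all(res$status == "ok"))
  expect_equal(res$insert, inserts)
})

test_that("ranking is count-descending with lexicographic tie-break", {
  rec <- tibble::tibble(
    sequence = c(strrep("T", 30), strrep("A", 30), strrep("C", 30)),
    count = c(3, 5, 3)
  )
  ranked <- rank_unique(rec)
  expect_equal(ranked$sequence[1], strrep("A", 30))
  expect_equal(ranked$sequence[2], strrep("C", 30)) # C < T at equal count
  expect_equal(sort(ranked$count), sort(rec$count)) # permutation of counts

  expect_equal(nrow(top_n_sequences(ranked, 1)), 1)
  expect_equal(top_n_sequences(ranked, 1)$sequence, strrep("A", 30))
  expect_equal(nrow(top_n_sequences(ranked, 100)), 3)
  expect_error(rank_unique(rec[0, ]), "non-empty")
})

test_that("k-mer profiles use overlapping windows and normalise to 1", {
  p1 <- kmer_profile(strrep("AC", 15), k = 1)
  expect_equal(p1$frequency[p1$kmer == "A"], 0.5)
  expect_equal(p1$frequency[p1$kmer == "C"], 0.5)
  expect_equal(sum(p1$frequency[p1$kmer %in% c("G", "T")]), 0)

  p2 <- kmer_profile(strrep("AC", 15), k = 2)
  expect_equal(p2$frequency[p2$kmer == "AC"], 15 / 29)
  expect_equal(p2$frequency[p2$kmer == "CA"], 14 / 29)
  expect_equal(nrow(p2), 16) # zeros kept

  pA <- kmer_profile(strrep("A", 30), k = 2)
  expect_equal(pA$frequency[pA$kmer == "AA"], 1)

  for (k in 1:5) {
    p <- kmer_profile(generate_initial_library(30, seed = k)$sequence, k = k)
    expect_equal(sum(p$frequency), 1, tolerance = 1e-9)
    expect_equal(nrow(p), 4^k)
  }
  expect_error(kmer_profile(strrep("A", 30), k = 6), "1..5")
})

test_that("k = 1 profile equals brute-force character counting", {
  lib <- generate_initial_library(100, counts_dist = "geometric", seed = 8)
  # count-weighted oracle: tally every character of every copy
  chars <- strsplit(lib$sequence, "")
  tally <- setNames(numeric(4), c("A", "C", "G", "T"))
  for (i in seq_along(chars)) {
    for (ch in chars[[i]]) tally[ch] <- tally[ch] + lib$count[i]
  }
  oracle <- tally / sum(tally)
  prof <- kmer_profile(lib, k = 1, weighting = "by_count")
  expect_equal(setNames(prof$frequency, prof$kmer), oracle, tolerance = 1e-12)
})

test_that("enrichment tables are per-round normalised profiles", {
  pure <- library_round(strrep("A", 30), 5, round_index = 6)
  et <- enrichment_table(list(pure), k = 1)
  expect_equal(et$frequency[et$kmer == "A"], 1)
  expect_equal(sum(et$frequency), 1)
  expect_equal(unique(et$round), 6)

  rounds <- simulate_selection(ac_model(), n_rounds = 3, n_unique = 2000,
                               n_draw = 2000, seed = 3)
  et <- enrichment_table(rounds, k = 1, n_top = 2000)
  ac <- et |>
    dplyr::filter(kmer %in% c("A", "C")) |>
    dplyr::group_by(round) |>
    dplyr::summarise(f = sum(frequency))
  expect_true(all(diff(ac$f) > 0))
  sums <- et |> dplyr::group_by(round) |> dplyr::summarise(s = sum(frequency))
  expect_true(all(abs(sums$s - 1) < 1e-9))
})
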