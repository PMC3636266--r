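base4 <- c("A", "C", "G", "T")
rand_seq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(base4, n, replace = TRUE),
                               collapse = ""))
}
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

lib2 <- repeat_library(tibble::tibble(
  name = c("satA", "elemB"),
  class = c("sat", "elem"),
  consensus = c(rand_seq(200, 1), rand_seq(150, 2))
))

test_that("exact seed matches are assigned and far reads stay unassigned", {
  read_exact <- paste0(substr(lib2$consensus[1], 1, 35), rand_seq(15, 3))
  # flip every third base of a satA seed -> 12 mismatches to satA everywhere
  seed_bases <- strsplit(substr(lib2$consensus[1], 1, 35), "")[[1]]
  flip <- seq(1, 35, by = 3)
  seed_bases[flip] <- vapply(seed_bases[flip],
                             function(b) setdiff(base4, b)[1], character(1))
  read_far <- paste0(paste(seed_bases, collapse = ""), rand_seq(15, 4))
  asn <- assign_reads_to_repeats(c(read_exact, read_far), lib2, rng_seed = 1)
  expect_equal(asn$repeat_name, c("satA", NA))
  expect_equal(asn$n_candidates, c(1L, 0L))
})

test_that("up to two seed mismatches are tolerated, three are not", {
  seed <- substr(lib2$consensus[2], 31, 65)
  mutate_at <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b) setdiff(base4, b)[1], character(1))
    paste(ch, collapse = "")
  }
  reads <- c(mutate_at(seed, c(5, 20)), mutate_at(seed, c(5, 20, 30)))
  reads <- paste0(reads, rand_seq(15, 5))
  asn <- assign_reads_to_repeats(reads, lib2, rng_seed = 1)
  expect_equal(asn$repeat_name, c("elemB", NA))
})

test_that("N never counts as a match", {
  seed <- substr(lib2$consensus[1], 1, 35)
  with_ns <- paste0("NNN", substr(seed, 4, 35), rand_seq(15, 6))
  asn <- assign_reads_to_repeats(with_ns, lib2, rng_seed = 1)
  expect_true(is.na(asn$repeat_name))
})

test_that("tandem-junction and reverse-complement seeds are found", {
  mono <- lib2$consensus[1]
  junction <- paste0(substr(mono, 184, 200), substr(mono, 1, 18))
  expect_equal(nchar(junction), 35)
  rc_read <- paste0(revcomp(substr(mono, 50, 84)), rand_seq(15, 7))
  asn <- assign_reads_to_repeats(
    c(paste0(junction, rand_seq(15, 8)), rc_read), lib2, rng_seed = 1
  )
  expect_equal(asn$repeat_name, c("satA", "satA"))
})

test_that("multireads split uniformly between tied entries", {
  shared <- rand_seq(60, 10)
  lib_tied <- repeat_library(tibble::tibble(
    name = c("e1", "e2"),
    class = c("c1", "c2"),
    consensus = c(paste0(shared, rand_seq(100, 11)),
                  paste0(rand_seq(100, 12), shared))
  ))
  read <- paste0(substr(shared, 1, 35), rand_seq(15, 13))
  picks <- vapply(1:2000, function(s) {
    assign_reads_to_repeats(read, lib_tied, rng_seed = s)$repeat_name
  }, character(1))
  expect_equal(sort(unique(picks)), c("e1", "e2"))
  phat <- mean(picks == "e1")
  expect_lt(abs(phat - 0.5), 2.576 * sqrt(0.25 / 2000))
  asn <- assign_reads_to_repeats(read, lib_tied, rng_seed = 1)
  expect_equal(asn$n_candidates, 2L)
})

test_that("percent_mapped divides class counts by the library total", {
  asn <- tibble::tibble(
    read_id = sprintf("r%d", 1:50),
    repeat_name = c(rep("satA", 40), rep("L1", 10)),
    class = c(rep("satMajor", 40), rep("L1", 10)),
    n_candidates = 1L
  )
  pm <- percent_mapped(asn, total_reads = 1000)
  expect_equal(pm$percent[pm$class == "satMajor"], 4.0)
  expect_equal(pm$percent[pm$class == "L1"], 1.0)

  pm0 <- percent_mapped(asn[0, ], total_reads = 100, library = lib2)
  expect_equal(pm0$percent, c(0, 0))

  two_entries <- tibble::tibble(
    read_id = sprintf("r%d", 1:20),
    repeat_name = c(rep("e1", 15), rep("e2", 5)),
    class = "satMajor", n_candidates = 1L
  )
  expect_equal(percent_mapped(two_entries, 400)$percent, 5.0)

  expect_error(percent_mapped(asn, total_reads = 0), "positive")
  expect_error(percent_mapped(asn, total_reads = 10), "smaller")
})

test_that("fold enrichment is the ratio of percents and flags zero input", {
  expect_equal(fold_enrichment(4, 1), 4)
  expect_equal(fold_enrichment(c(2, 5), c(2, 5)), c(1, 1))
  expect_warning(out <- fold_enrichment(3, 0), "undefined")
  expect_true(is.na(out))
})

test_that("the exact test matches exhaustive hypergeometric enumeration", {
  expect_equal(repeat_exact_test(10, 1000, 10, 1000), 1.0)
  p <- repeat_exact_test(30, 1000, 10, 1000)
  expect_equal(p, fisher_oracle(30, 970, 10, 990), tolerance = 1e-12)
  p2 <- repeat_exact_test(100, 1000, 0, 1000)
  expect_equal(p2, fisher_oracle(100, 900, 0, 1000), tolerance = 1e-10)
  expect_lt(p2, 1e-20)
  # row-swap symmetry
  expect_equal(repeat_exact_test(30, 1000, 10, 1000),
               repeat_exact_test(10, 1000, 30, 1000))
  expect_error(repeat_exact_test(-1, 10, 1, 10), "non-negative")
  expect_error(repeat_exact_test(11, 10, 1, 10), "exceed")
})

test_that("the enrichment table is self-consistent and 1.0 against itself", {
  b <- build_genome(
    genome_spec(c(chr1 = 30000),
                repeats = tibble::tibble(name = "satA", class = "sat",
                                         chrom = "chr1", start = 10000,
                                         monomer = satellite_monomer(200, 21),
                                         copies = 25, divergence = 0.02)),
    seed = 21
  )
  lib <- repeat_library(tibble::tibble(
    name = "satA", class = "sat",
    consensus = satellite_monomer(200, 21)
  ))
  reads <- simulate_library(b$genome, b$features, n_reads = 4000, seed = 22)
  asn <- assign_reads_to_repeats(reads, lib, rng_seed = 23)
  tab <- repeat_enrichment_table(asn, asn, 4000, 4000, library = lib)
  expect_equal(tab$fold, 1.0)
  expect_equal(tab$p_value, 1.0)
  expect_lte(sum(tab$chip_in), 4000)
  expect_equal(sum(!is.na(asn$repeat_name)), tab$chip_in)
})
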