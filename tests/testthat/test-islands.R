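# Raw-count track at the island window size with an explicit total (so the
# background rate lambda is under the test's control).
island_track <- function(counts, total, w = 200L) {
  make_track(counts, w = w, norm = "raw", total_reads = total)
}

params_nofdr <- function(gap = 600L, ...) {
  island_params(gap = gap, n_background = 0L, ...)
}

test_that("an isolated spike yields a single one-window island", {
  counts <- rep(0, 40)
  counts[17] <- 50
  # lambda = total * w / (0.8 * genome): total 16 reads over 8000 bp -> 0.5
  tr <- island_track(counts, total = 50)
  isl <- call_islands(tr, params = params_nofdr(), seed = 1)
  expect_equal(nrow(isl), 1)
  expect_equal(c(isl$start, isl$end), c(16 * 200, 17 * 200))
  expect_equal(isl$n_eligible, 1L)
})

test_that("the gap rule merges at 600 bp and splits at 800 bp", {
  base <- rep(0, 40)
  sep600 <- base
  sep600[c(10, 14)] <- 40  # 3 ineligible windows = 600 bp between
  tr <- island_track(sep600, total = 80)
  isl <- call_islands(tr, params = params_nofdr(gap = 600L), seed = 1)
  expect_equal(nrow(isl), 1)
  expect_equal(c(isl$start, isl$end), c(9 * 200, 14 * 200))

  sep800 <- base
  sep800[c(10, 15)] <- 40  # 4 ineligible windows = 800 bp between
  tr2 <- island_track(sep800, total = 80)
  isl2 <- call_islands(tr2, params = params_nofdr(gap = 600L), seed = 1)
  expect_equal(nrow(isl2), 2)
})

test_that("random small tracks match the brute-force cluster oracle", {
  for (s in 1:25) {
    counts <- withr::with_seed(1000 + s, rpois(sample(10:30, 1), 2))
    total <- sum(counts)
    if (total == 0) next
    tr <- island_track(counts, total = total)
    lambda <- total * 200 / (0.8 * length(counts) * 200)
    for (gap in c(0L, 200L, 400L, 600L)) {
      isl <- call_islands(tr, params = params_nofdr(gap = gap), seed = 1)
      oracle <- island_oracle(counts, lambda, 0.2, gap, 200L)
      expect_equal(isl$start, oracle$start)
      expect_equal(isl$end, oracle$end)
    }
  }
})

test_that("islands are maximal and nest as the gap grows", {
  counts <- withr::with_seed(77, rpois(60, 3))
  tr <- island_track(counts, total = sum(counts))
  lambda <- sum(counts) * 200 / (0.8 * 60 * 200)
  p_el <- ppois(counts - 1, lambda, lower.tail = FALSE) <= 0.2
  prev <- NULL
  for (gap in c(0L, 200L, 400L, 600L)) {
    isl <- call_islands(tr, params = params_nofdr(gap = gap), seed = 1)
    # maximality: the window just outside each island boundary cannot be
    # eligible, nor can an eligible window sit within the gap budget outside
    for (i in seq_len(nrow(isl))) {
      lo <- isl$start[i] / 200
      hi <- isl$end[i] / 200
      g <- gap / 200
      if (lo >= 1) {
        expect_false(any(p_el[seq(max(1, lo - g), lo)]))
      }
      if (hi < 60) {
        expect_false(any(p_el[seq(hi + 1, min(60, hi + 1 + g))]))
      }
    }
    if (!is.null(prev)) {
      # every smaller-gap island is contained in exactly one larger-gap island
      for (i in seq_len(nrow(prev))) {
        container <- sum(isl$start <= prev$start[i] & isl$end >= prev$end[i])
        expect_equal(container, 1)
      }
    }
    prev <- isl
  }
})

test_that("gap optimization maximizes aggregate score with ties to smallest", {
  counts <- rep(0, 40)
  counts[20] <- 50
  tr <- island_track(counts, total = 50)
  opt <- optimize_gap(tr, params = params_nofdr(), seed = 1)
  expect_equal(opt$best_gap, 0)
  expect_equal(nrow(opt$diagnostics), 4)
  expect_true(all(diff(opt$diagnostics$aggregate_score) >= 0))

  two <- rep(0, 40)
  two[c(10, 13)] <- 40  # 400 bp of ineligible space between
  tr2 <- island_track(two, total = 80)
  opt2 <- optimize_gap(tr2, params = params_nofdr(), seed = 1)
  d <- opt2$diagnostics
  expect_equal(d$n_islands[d$gap %in% c(0, 200)], c(2L, 2L))
  expect_equal(d$n_islands[d$gap %in% c(400, 600)], c(1L, 1L))
  # manual recount: aggregate score equals the sum over called islands
  isl400 <- call_islands(tr2, params = params_nofdr(gap = 400L), seed = 1)
  expect_equal(d$aggregate_score[d$gap == 400], sum(isl400$score))
})

test_that("the Monte Carlo E-value budget holds on uniform reads", {
  # E = 2 with a seeded background: the mean retained-island count over
  # uniform-read tracks should not exceed E by more than 3 SE
  n_rep <- 30
  counts_of <- function(s) {
    withr::with_seed(2000 + s, as.vector(stats::rmultinom(1, 400,
                                                          rep(1 / 100, 100))))
  }
  kept <- vapply(seq_len(n_rep), function(s) {
    tr <- island_track(counts_of(s), total = 400)
    p <- island_params(evalue = 2, n_background = 10L)
    nrow(call_islands(tr, params = p, seed = 3000 + s))
  }, numeric(1))
  se <- stats::sd(kept) / sqrt(n_rep)
  expect_lte(mean(kept), 2 + 3 * se)
})

test_that("FDR filtering against the input track keeps real enrichment only", {
  counts <- rep(1, 50)
  counts[25] <- 60
  chip <- island_track(counts, total = sum(counts))
  input <- island_track(rep(1, 50), total = 50)
  isl <- call_islands(chip, input, params = params_nofdr(), seed = 1)
  expect_equal(nrow(isl), 1)
  expect_true(all(isl$q <= 0.001))
})

test_that("common/unique decomposition follows the 1-bp overlap rule", {
  a <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  cu_same <- common_unique(a, a)
  expect_equal(nrow(cu_same$common), 1)
  expect_equal(nrow(cu_same$a_unique), 0)

  b_far <- tibble::tibble(chrom = "chr1", start = 5000, end = 6000)
  cu_dis <- common_unique(a, b_far)
  expect_equal(nrow(cu_dis$common), 0)
  expect_equal(nrow(cu_dis$a_unique), 1)
  expect_equal(nrow(cu_dis$b_unique), 1)

  b <- tibble::tibble(chrom = "chr1", start = 800, end = 2000)
  cu <- common_unique(a, b)
  expect_equal(c(cu$common$start, cu$common$end), c(800, 1000))
  expect_equal(nrow(cu$a_unique), 0)
  expect_equal(nrow(cu$b_unique), 0)
})

test_that("region annotation partitions by midpoint location", {
  genes <- make_genes(starts = c(50000, 100000), ends = c(60000, 110000),
                      expression = 1)
  regions <- tibble::tibble(
    chrom = "chr1",
    start = c(54000, 46000, 200000),
    end = c(56000, 48000, 201000)
  )
  ann <- annotate_regions(regions, genes, proximal_flank = 5000)
  expect_equal(ann$regions$category, c("gene", "proximal", "distal"))
  expect_equal(sum(ann$breakdown$fraction), 1)
})

test_that("top-fraction selection ranks by score with stable genomic ties", {
  isl <- tibble::tibble(
    chrom = "chr1",
    start = seq(0, by = 1000, length.out = 100),
    end = seq(500, by = 1000, length.out = 100),
    score = withr::with_seed(5, sample(rep(1:20, 5)))
  )
  top <- top_fraction_regions(isl, 0.10)
  expect_equal(nrow(top), 10)
  all_of_them <- top_fraction_regions(isl, 1.0)
  expect_equal(dplyr::arrange(all_of_them, start), dplyr::arrange(isl, start))

  # oracle: stable sort by (-score, chrom, start)
  oracle <- isl[order(-isl$score, isl$chrom, isl$start), ][1:10, ]
  expect_equal(top, oracle)
})
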