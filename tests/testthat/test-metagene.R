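test_that("expression partitions pick extremes and equal quintiles", {
  g <- make_genes(starts = seq(0, 900, by = 100) * 10 + 1000,
                  ends = seq(0, 900, by = 100) * 10 + 3000,
                  expression = 1:10)
  grp <- partition_by_expression(g, "deciles_extremes")
  expect_equal(grp$gene_id[grp$group == "top10"], "g10")
  expect_equal(grp$gene_id[grp$group == "bottom10"], "g01")
  expect_equal(sum(grp$group == "all"), 10)

  g100 <- make_genes(starts = seq_len(100) * 5000,
                     ends = seq_len(100) * 5000 + 2000,
                     expression = withr::with_seed(1, runif(100)))
  q <- partition_by_expression(g100, "quintiles")
  expect_equal(as.integer(table(q$group)), rep(20L, 5))

  g6 <- make_genes(starts = seq_len(6) * 5000, ends = seq_len(6) * 5000 + 200,
                   expression = rep(0, 6))
  q6 <- partition_by_expression(g6, "quintiles")
  expect_equal(as.integer(table(q6$group)[paste0("q", 1:5)]), c(2L, 1L, 1L, 1L, 1L))
  # ties resolved by stable gene id: the first two ids land in q1
  expect_equal(sort(q6$gene_id[q6$group == "q1"]), c("g01", "g02"))
  expect_error(partition_by_expression(g6[0, ]), "empty")
})

test_that("mark partitions follow the promoter score ranking", {
  tr <- make_track(rep(5, 50), w = 100)
  g <- make_genes(starts = c(500, 1500, 2500, 3500), ends = c(900, 1900, 2900, 3900),
                  expression = 1)
  grp <- partition_by_mark(g, tr, k = 2, tss_halfwidth = 200)
  expect_equal(as.integer(table(grp$group)), c(2L, 2L))
  expect_equal(unique(grp$score), 5)

  # strictly increasing score with gene id -> g1 holds the lowest scorers
  tr2 <- make_track(seq_len(50), w = 100)
  grp2 <- partition_by_mark(g, tr2, k = 2, tss_halfwidth = 200)
  expect_equal(sort(grp2$gene_id[grp2$group == "g1"]), c("g01", "g02"))

  # 100 genes against an independent sort-and-slice oracle
  g100 <- make_genes(starts = seq_len(100) * 400, ends = seq_len(100) * 400 + 200,
                     expression = 1)
  tr3 <- make_track(withr::with_seed(2, rnorm(450)), w = 100)
  grp3 <- partition_by_mark(g100, tr3, k = 5, tss_halfwidth = 100)
  oracle <- grp3$gene_id[order(grp3$score, grp3$gene_id)]
  expected <- rep(paste0("g", 1:5), each = 20)
  lookup <- stats::setNames(expected, oracle)
  expect_equal(unname(lookup[grp3$gene_id]), grp3$group)
})

test_that("bivalency classes come from half-open promoter overlap", {
  g <- make_genes(starts = 5000, ends = 7000, expression = 1)
  both <- classify_bivalent(
    g, tibble::tibble(chrom = "chr1", start = 4900, end = 5100),
    tibble::tibble(chrom = "chr1", start = 4000, end = 4500),
    tss_halfwidth = 1000
  )
  expect_equal(both$group, "K4+K27+")

  none <- classify_bivalent(g, tibble::tibble(chrom = character(),
                                              start = numeric(),
                                              end = numeric()),
                            tibble::tibble(chrom = character(),
                                           start = numeric(),
                                           end = numeric()))
  expect_equal(none$group, "K4-K27-")

  # promoter window is [tss - hw, tss + hw): a region starting exactly at
  # tss + hw only touches and does not overlap
  touch <- classify_bivalent(
    g, tibble::tibble(chrom = "chr1", start = 6000, end = 6500),
    tibble::tibble(chrom = "chr1", start = 3500, end = 4000),
    tss_halfwidth = 1000
  )
  expect_equal(touch$group, "K4-K27-")
})

test_that("metagene profiles average gene-relative bins with strand flips", {
  const <- make_track(rep(3.5, 120), w = 100)
  g <- make_genes(starts = c(4000, 7000), ends = c(5000, 8000),
                  expression = c(1, 2))
  prof <- metagene_profile(const, g, flank = 1000, bin = 100)
  expect_equal(unique(prof$mean), 3.5)
  expect_equal(nrow(prof), 2 * 1000 / 100)

  # hand-laid track, two plus-strand genes with TSS on the grid
  vals <- seq_len(120)
  tr <- make_track(vals, w = 100)
  prof2 <- metagene_profile(tr, g, flank = 200, bin = 100)
  # gene TSSs at 4000 and 7000 -> windows 41 and 71 at offset 0
  expect_equal(prof2$mean, c((39 + 69) / 2, (40 + 70) / 2, (41 + 71) / 2,
                             (42 + 72) / 2))

  # a minus-strand gene must equal the plus-strand run on the mirrored track
  gm <- make_genes(starts = 4000, ends = 5000, strand = "-", expression = 1)
  profm <- metagene_profile(tr, gm, flank = 300, bin = 100)
  mirrored <- make_track(rev(vals), w = 100)
  gp <- make_genes(starts = 12000 - 5000, ends = 12000 - 4000, strand = "+",
                   expression = 1)
  profp <- metagene_profile(mirrored, gp, flank = 300, bin = 100)
  expect_equal(profm$mean, profp$mean)
})

test_that("profiles of merged groups are gene-count-weighted means", {
  tr <- make_track(withr::with_seed(3, rnorm(200)), w = 100)
  g <- make_genes(starts = seq_len(12) * 1500, ends = seq_len(12) * 1500 + 500,
                  expression = seq_len(12))
  ga <- tibble::tibble(gene_id = g$gene_id[1:4], group = "A")
  gb <- tibble::tibble(gene_id = g$gene_id[5:12], group = "B")
  gu <- tibble::tibble(gene_id = g$gene_id, group = "U")
  pa <- metagene_profile(tr, g, ga, flank = 500, bin = 100)
  pb <- metagene_profile(tr, g, gb, flank = 500, bin = 100)
  pu <- metagene_profile(tr, g, gu, flank = 500, bin = 100)
  expect_equal(pu$mean, (4 * pa$mean + 8 * pb$mean) / 12)
})

test_that("distal decay drops points near other promoters", {
  tr <- make_track(rep(2, 300), w = 100)
  g1 <- make_genes(starts = 10000, ends = 12000, expression = 1)
  d1 <- distal_decay(tr, g1, distances = c(0, 1000, 5000),
                     exclusion_radius = 1000)
  expect_equal(nrow(d1), 5)  # -5000,-1000,0,1000,5000
  expect_equal(unique(d1$value), 2)

  g2 <- make_genes(starts = c(10000, 10500), ends = c(10200, 10700),
                   expression = c(1, 2))
  d2 <- distal_decay(tr, g2, distances = c(100, 300, 500),
                     exclusion_radius = 1000)
  expect_equal(nrow(d2), 0)
})
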