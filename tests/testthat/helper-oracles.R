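# Independent oracles and tiny fixture builders used across the suite.

# Exhaustive two-sided hypergeometric p for a 2x2 table with fixed margins:
# sum the probabilities of all tables (over the support of the top-left cell)
# no more likely than the observed one, with the conventional (1 + 1e-7)
# relative guard for floating ties of exactly symmetric tables.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  probs <- exp(logp)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Brute-force island enumeration: given window counts, background rate and
# eligibility cutoff, walk the windows left to right, opening an island at
# each eligible window and extending it while the run of consecutive
# ineligible windows stays within the gap budget.
island_oracle <- function(counts, lambda, p0, gap_bp, w) {
  p <- ppois(counts - 1, lambda, lower.tail = FALSE)
  eligible <- p <= p0
  max_skip <- gap_bp %/% w
  islands <- list()
  i <- 1
  n <- length(counts)
  while (i <= n) {
    if (!eligible[i]) {
      i <- i + 1
      next
    }
    from <- i
    to <- i
    j <- i + 1
    skipped <- 0
    while (j <= n && skipped < max_skip + 1) {
      if (eligible[j]) {
        to <- j
        skipped <- 0
      } else {
        skipped <- skipped + 1
      }
      j <- j + 1
    }
    islands[[length(islands) + 1]] <- c(from = from, to = to)
    i <- to + 1
  }
  if (length(islands) == 0) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  m <- do.call(rbind, islands)
  tibble::tibble(start = unname((m[, "from"] - 1L) * w),
                 end = unname(m[, "to"] * w))
}

# Signal track with given per-window values on one chromosome.
make_track <- function(values, w = 100L, chrom = "chr1", norm = "raw",
                       total_reads = NA_real_) {
  len <- length(values) * w
  new_signal_track(
    tibble::tibble(chrom = chrom, start = seq(0L, by = w,
                                              length.out = length(values)),
                   value = as.numeric(values)),
    window = w, norm = norm, chrom_sizes = stats::setNames(len, chrom),
    total_reads = total_reads
  )
}

# Small gene table on one chromosome; tss/tts from 0-based half-open spans.
make_genes <- function(starts, ends, strand = "+", expression = NULL,
                       chrom = "chr1") {
  n <- length(starts)
  strand <- rep_len(strand, n)
  tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n)),
    chrom = chrom,
    strand = strand,
    tss = ifelse(strand == "+", starts, ends - 1L),
    tts = ifelse(strand == "+", ends - 1L, starts),
    expression = expression %||% rep(1, n)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
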