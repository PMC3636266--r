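#' Island-calling parameters
#'
#' Parameters of the SICER-style window-cluster caller: 200-bp scoring
#' windows, eligible windows merged across gaps of up to 600 bp of ineligible
#' space, an E-value of 1000 against a uniform-background expectation, an
#' effective (mappable) genome fraction of 0.8, and an FDR threshold of 0.001
#' against islands called on the input library. The window-eligibility
#' Poisson p-value cutoff `p0 = 0.2` is the published SICER default.
#'
#' @param window Scoring window `w` in bp.
#' @param gap Maximum ineligible gap to bridge, in bp; a multiple of `window`
#'   between 0 and `3 * window`.
#' @param evalue E-value: tolerated expected number of equally scoring
#'   islands under a uniform background (`Inf` disables the score threshold).
#' @param effective_fraction Effective (mappable) genome fraction in (0, 1].
#' @param q_threshold Benjamini-Hochberg q-value cutoff vs the input library.
#' @param p0 Window-eligibility upper-tail Poisson p cutoff.
#' @param n_background Number of Monte Carlo background replicates used to
#'   realize the E-value threshold (0 disables it).
#' @return An `island_params` list.
#' @export
island_params <- function(window = 200L, gap = 600L, evalue = 1000,
                          effective_fraction = 0.8, q_threshold = 0.001,
                          p0 = 0.2, n_background = 10L) {
  stopifnot(window > 0, gap >= 0, evalue > 0,
            effective_fraction > 0, effective_fraction <= 1,
            q_threshold > 0, q_threshold <= 1, p0 > 0, p0 <= 1,
            n_background >= 0)
  if (gap %% window != 0 || gap > 3 * window) {
    abort("gap must be a multiple of window in {0, w, 2w, 3w}")
  }
  structure(list(window = as.integer(window), gap = as.integer(gap),
                 evalue = evalue, effective_fraction = effective_fraction,
                 q_threshold = q_threshold, p0 = p0,
                 n_background = as.integer(n_background)),
            class = "island_params")
}

# Eligible windows and their -ln Poisson p scores for one count vector.
window_eligibility <- function(counts, lambda, p0) {
  p <- ppois(counts - 1, lambda, lower.tail = FALSE)
  list(eligible = p <= p0, nlp = -log(p))
}

# Merge eligible windows separated by <= gap bp of ineligible space into
# maximal clusters; returns a tibble of window-index runs [from, to]
# (1-based, inclusive) with score and eligible-window count.
cluster_eligible <- function(eligible, nlp, w, gap) {
  idx <- which(eligible)
  if (length(idx) == 0) {
    return(tibble(from = integer(), to = integer(), score = double(),
                  n_eligible = integer()))
  }
  max_skip <- gap %/% w  # ineligible windows bridgeable
  new_island <- c(TRUE, diff(idx) - 1L > max_skip)
  grp <- cumsum(new_island)
  tibble(idx = idx, nlp = nlp[idx], grp = grp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(from = min(.data$idx), to = max(.data$idx),
                     score = sum(.data$nlp), n_eligible = dplyr::n(),
                     .groups = "drop") |>
    dplyr::select(-"grp") |>
    dplyr::select("from", "to", "score", "n_eligible")
}

# Island calling core (eligibility + clustering) over a whole track.
call_islands_core <- function(track, lambda, p0, gap) {
  w <- track_window(track)
  out <- purrr::imap_dfr(split(track$value, track$chrom), function(v, ch) {
    el <- window_eligibility(v, lambda, p0)
    cl <- cluster_eligible(el$eligible, el$nlp, w, gap)
    if (nrow(cl) == 0) return(NULL)
    tibble(chrom = ch, start = (cl$from - 1L) * w, end = cl$to * w,
           score = cl$score, n_eligible = cl$n_eligible)
  })
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  score = double(), n_eligible = integer())
  }
  out
}

#' Call enrichment islands from windowed read counts
#'
#' SICER-style calling: (1) the background rate per window is
#' `lambda = total_reads * w / (effective_fraction * genome_length)`;
#' (2) a window is eligible if its count's upper-tail Poisson p-value at
#' `lambda` is at most `p0`; (3) eligible windows separated by at most `gap`
#' bp of ineligible space merge into one island; (4) the island score is the
#' sum of `-ln p` over its eligible windows; (5) the score threshold is set
#' so that the expected number of islands at or above it in a seeded Monte
#' Carlo uniform background (same read count over the effective genome) is at
#' most the E-value; (6) when an input track is supplied, each island gets an
#' empirical tail probability against the score distribution of islands
#' called identically on the input, Benjamini-Hochberg adjusted, and islands
#' with `q <= q_threshold` are kept.
#'
#' @param chip Raw-count `signal_track` at window `params$window`.
#' @param input Optional raw-count input `signal_track` (enables the FDR
#'   filter).
#' @param params An [island_params()].
#' @param seed Integer seed for the Monte Carlo background.
#' @return An `island_set` tibble: `chrom`, `start`, `end`, `score`,
#'   `n_eligible`, and `q` when `input` is given; sorted by genomic position.
#' @export
call_islands <- function(chip, input = NULL, params = island_params(),
                         seed = 1L) {
  w <- track_window(chip)
  if (w != params$window) {
    abort("chip track window differs from params$window")
  }
  genome_len <- sum(track_chrom_sizes(chip))
  total <- track_total_reads(chip)
  if (is.na(total)) total <- sum(chip$value)
  lambda <- total * w / (params$effective_fraction * genome_len)
  if (lambda <= 0) abort("background rate lambda is zero (empty chip track)")
  islands <- call_islands_core(chip, lambda, params$p0, params$gap)
  if (nrow(islands) == 0) {
    return(empty_island_set(params, !is.null(input)))
  }
  if (is.finite(params$evalue) && params$n_background > 0) {
    s_e <- mc_score_threshold(total, genome_len, w, params, seed)
    islands <- dplyr::filter(islands, .data$score >= s_e)
  }
  if (!is.null(input)) {
    if (track_window(input) != w) {
      abort("input track window differs from chip track window")
    }
    in_total <- track_total_reads(input)
    if (is.na(in_total)) in_total <- sum(input$value)
    in_lambda <- in_total * w / (params$effective_fraction * genome_len)
    in_scores <- call_islands_core(input, in_lambda, params$p0,
                                   params$gap)$score
    p_emp <- purrr::map_dbl(islands$score, function(s) {
      sum(in_scores >= s) / max(1L, length(in_scores))
    })
    islands$q <- p.adjust(p_emp, method = "BH")
    islands <- dplyr::filter(islands, .data$q <= params$q_threshold)
  }
  islands <- dplyr::arrange(islands, match(.data$chrom,
                                           names(track_chrom_sizes(chip))),
                            .data$start)
  structure(islands, params = params,
            class = c("island_set", class(tibble())))
}

empty_island_set <- function(params, with_q) {
  out <- tibble(chrom = character(), start = integer(), end = integer(),
                score = double(), n_eligible = integer())
  if (with_q) out$q <- double()
  structure(out, params = params, class = c("island_set", class(tibble())))
}

# Monte Carlo realization of the E-value score threshold: reads placed
# uniformly over the effective genome, islands called with the same
# eligibility/gap rules; the threshold is the smallest score whose expected
# exceedance count per replicate is <= E.
mc_score_threshold <- function(total_reads, genome_len, w, params, seed) {
  n_win <- ceiling(params$effective_fraction * genome_len / w)
  lambda <- total_reads / n_win
  scores <- with_seed(seed, {
    purrr::map(seq_len(params$n_background), function(b) {
      counts <- as.vector(stats::rmultinom(1, total_reads,
                                           rep(1 / n_win, n_win)))
      el <- window_eligibility(counts, lambda, params$p0)
      cluster_eligible(el$eligible, el$nlp, w, params$gap)$score
    }) |> unlist()
  })
  budget <- params$evalue * params$n_background
  if (length(scores) <= budget) return(0)
  sorted <- sort(scores, decreasing = TRUE)
  # smallest s with #{background >= s} <= E * B: just above the
  # (budget + 1)-th largest background score
  sorted[floor(budget) + 1] + sqrt(.Machine$double.eps)
}

#' Optimize the island gap size
#'
#' Calls islands at each candidate gap and picks the gap maximizing the
#' aggregate score (sum of scores of the retained islands); ties go to the
#' smallest gap.
#'
#' @inheritParams call_islands
#' @param gaps Candidate gaps in bp (multiples of the window).
#' @return List with `best_gap` and `diagnostics` (tibble: `gap`,
#'   `n_islands`, `aggregate_score`).
#' @export
optimize_gap <- function(chip, input = NULL, params = island_params(),
                         gaps = params$window * 0:3, seed = 1L) {
  diag <- purrr::map_dfr(gaps, function(g) {
    p <- params
    p$gap <- as.integer(g)
    isl <- call_islands(chip, input, p, seed = seed)
    tibble(gap = g, n_islands = nrow(isl),
           aggregate_score = sum(isl$score))
  })
  best <- diag$gap[order(-diag$aggregate_score, diag$gap)][1]
  list(best_gap = best, diagnostics = diag)
}

#' Common and unique regions of two island sets
#'
#' Two islands are considered shared if they overlap by at least 1 bp;
#' `common` holds the intersected spans of all overlapping pairs, `a_unique`
#' and `b_unique` the islands of each set with zero overlap in the other.
#'
#' @param a,b Island tibbles (`chrom`, `start`, `end`).
#' @return List of tibbles: `common`, `a_unique`, `b_unique`.
#' @export
common_unique <- function(a, b) {
  a <- as_tibble(a)
  b <- as_tibble(b)
  per_chrom <- function(ac, bc) {
    ra <- IRanges::IRanges(ac$start + 1L, ac$end)
    rb <- IRanges::IRanges(bc$start + 1L, bc$end)
    ov <- IRanges::findOverlaps(ra, rb, minoverlap = 1L)
    list(
      common_idx = ov,
      inter = IRanges::pintersect(ra[S4Vectors::queryHits(ov)],
                                  rb[S4Vectors::subjectHits(ov)]),
      a_hit = unique(S4Vectors::queryHits(ov)),
      b_hit = unique(S4Vectors::subjectHits(ov))
    )
  }
  chroms <- union(unique(a$chrom), unique(b$chrom))
  parts <- purrr::map(chroms, function(ch) {
    ac <- a[a$chrom == ch, ]
    bc <- b[b$chrom == ch, ]
    r <- per_chrom(ac, bc)
    list(
      common = if (length(r$inter) > 0) {
        red <- IRanges::reduce(r$inter)
        tibble(chrom = ch, start = IRanges::start(red) - 1L,
               end = IRanges::end(red))
      },
      a_unique = ac[setdiff(seq_len(nrow(ac)), r$a_hit), ],
      b_unique = bc[setdiff(seq_len(nrow(bc)), r$b_hit), ]
    )
  })
  list(
    common = dplyr::bind_rows(purrr::map(parts, "common")),
    a_unique = dplyr::bind_rows(purrr::map(parts, "a_unique")),
    b_unique = dplyr::bind_rows(purrr::map(parts, "b_unique"))
  )
}

#' Annotate regions as genic, proximal, or distal
#'
#' Each region is assigned by its midpoint: inside any TSS-TTS gene span it
#' is `gene`; within `proximal_flank` bp of a gene boundary it is `proximal`
#' (regulatory); otherwise `distal` (intergenic). Fractions sum to 1.
#'
#' @param regions Tibble of intervals (`chrom`, `start`, `end`).
#' @param genes A [gene_table()].
#' @param proximal_flank Proximal flank in bp.
#' @return List with `regions` (input plus `category`) and `breakdown`
#'   (tibble: `category`, `n`, `fraction`).
#' @export
annotate_regions <- function(regions, genes, proximal_flank = 5000L) {
  regions <- as_tibble(regions)
  genes <- gene_table(genes)
  if (nrow(regions) == 0) {
    return(list(regions = dplyr::mutate(regions, category = character(0)),
                breakdown = tibble(category = character(), n = integer(),
                                   fraction = double())))
  }
  span_start <- pmin(genes$tss, genes$tts)
  span_end <- pmax(genes$tss, genes$tts) + 1L  # half-open gene span
  mid <- floor((regions$start + regions$end) / 2)
  category <- purrr::map2_chr(regions$chrom, mid, function(ch, m) {
    on <- genes$chrom == ch
    if (!any(on)) return("distal")
    s <- span_start[on]
    e <- span_end[on]
    if (any(m >= s & m < e)) return("gene")
    dist <- pmin(abs(m - s), abs(m - (e - 1L)))
    if (any(dist <= proximal_flank)) "proximal" else "distal"
  })
  regions$category <- category
  breakdown <- tibble(category = c("gene", "proximal", "distal")) |>
    dplyr::left_join(dplyr::count(regions, .data$category),
                     by = "category") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  fraction = .data$n / sum(.data$n))
  list(regions = regions, breakdown = breakdown)
}

#' Select the top-scoring fraction of islands
#'
#' Islands ranked by score descending; the top `ceiling(fraction * N)` are
#' returned, with ties at the cut broken by genomic order (chromosome, then
#' start).
#'
#' @param islands An island tibble with a `score` column.
#' @param fraction Fraction in (0, 1].
#' @return The selected islands, highest score first.
#' @export
top_fraction_regions <- function(islands, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1)
  islands <- as_tibble(islands)
  if (nrow(islands) == 0) return(islands)
  k <- ceiling(fraction * nrow(islands))
  islands[order(-islands$score, islands$chrom, islands$start), ][seq_len(k), ]
}
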