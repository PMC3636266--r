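#' Validate a gene table
#'
#' The gene table drives all metagene partitions: one row per gene with
#' `gene_id`, `chrom`, `strand`, `tss`, `tts` (0-based base coordinates; on
#' the minus strand the TSS is the larger coordinate), and a non-negative
#' `expression` value.
#'
#' @param genes Tibble (or TSV-derived data frame) with the columns above.
#' @return The validated tibble.
#' @export
gene_table <- function(genes) {
  genes <- as_tibble(genes)
  stopifnot(all(c("gene_id", "chrom", "strand", "tss", "tts", "expression")
                %in% names(genes)))
  if (any(genes$tss == genes$tts)) abort("TSS must differ from TTS")
  if (!all(genes$strand %in% c("+", "-"))) abort("strand must be + or -")
  minus <- genes$strand == "-"
  if (any(genes$tss[!minus] > genes$tts[!minus]) ||
      any(genes$tss[minus] < genes$tts[minus])) {
    abort("TSS/TTS orientation inconsistent with strand")
  }
  if (any(genes$expression < 0)) abort("expression must be >= 0")
  genes
}

# Equal rank-based split into k groups ordered ascending by `score` with ties
# broken by stable gene id; the first groups absorb the remainder, so sizes
# differ by at most one.
rank_groups <- function(gene_id, score, k, labels = NULL) {
  n <- length(gene_id)
  ord <- order(score, gene_id)
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  labels <- labels %||% paste0("g", seq_len(k))
  grp <- character(n)
  grp[ord] <- rep(labels, times = sizes)
  grp
}

#' Partition genes by expression level
#'
#' `"deciles_extremes"` returns the groups used for highly-active vs silent
#' comparisons: `top10` (top 10% by expression), `bottom10` (bottom 10%), and
#' `all` (every gene) — a gene can appear in two groups. `"quintiles"` is a
#' true partition into 5 rank-based equal groups `q1` (lowest expression) to
#' `q5` (highest); ties are broken by stable gene-id order and the lower
#' groups absorb any remainder.
#'
#' @param genes A [gene_table()].
#' @param scheme `"deciles_extremes"` or `"quintiles"`.
#' @return A gene grouping: tibble with `gene_id`, `group`, and a `scheme`
#'   attribute.
#' @export
partition_by_expression <- function(genes,
                                    scheme = c("deciles_extremes",
                                               "quintiles")) {
  scheme <- match.arg(scheme)
  genes <- gene_table(genes)
  if (nrow(genes) == 0) abort("empty gene table")
  if (scheme == "deciles_extremes" && nrow(genes) < 10) {
    abort("need at least 10 genes for decile extremes")
  }
  if (scheme == "quintiles" && nrow(genes) < 5) {
    abort("need at least 5 genes for quintiles")
  }
  out <- if (scheme == "deciles_extremes") {
    k <- ceiling(nrow(genes) / 10)
    ord <- order(genes$expression, genes$gene_id)
    dplyr::bind_rows(
      tibble(gene_id = genes$gene_id[rev(ord)][seq_len(k)], group = "top10"),
      tibble(gene_id = genes$gene_id[ord][seq_len(k)], group = "bottom10"),
      tibble(gene_id = genes$gene_id, group = "all")
    )
  } else {
    tibble(
      gene_id = genes$gene_id,
      group = rank_groups(genes$gene_id, genes$expression, 5L,
                          labels = paste0("q", 1:5))
    )
  }
  structure(out, scheme = scheme, class = class(tibble()))
}

#' Partition genes by promoter histone-mark level
#'
#' Scores each gene by its mean mark signal over `TSS +/- tss_halfwidth`
#' (overlap-weighted window mean, clipped to the chromosome) and splits the
#' ranked genes into `k` equal groups, `g1` (lowest) to `gk` (highest).
#'
#' @param genes A [gene_table()].
#' @param mark_track A `signal_track` of the histone mark.
#' @param k Number of groups (>= 2).
#' @param tss_halfwidth Half-width of the promoter scoring window in bp.
#' @return Gene grouping tibble (`gene_id`, `group`, `score`).
#' @export
partition_by_mark <- function(genes, mark_track, k = 5L,
                              tss_halfwidth = 2000L) {
  if (k < 2) abort("k must be >= 2")
  genes <- gene_table(genes)
  if (nrow(genes) == 0) abort("empty gene table")
  sizes <- track_chrom_sizes(mark_track)
  regions <- tibble(
    chrom = genes$chrom,
    start = pmax(0, genes$tss - tss_halfwidth),
    end = pmin(unname(sizes[genes$chrom]), genes$tss + tss_halfwidth)
  )
  score <- region_signal(mark_track, regions)$signal
  tibble(gene_id = genes$gene_id, score = score,
         group = rank_groups(genes$gene_id, score, k))
}

#' Classify promoters by bivalency
#'
#' Four classes by whether `TSS +/- tss_halfwidth` (half-open) overlaps at
#' least 1 bp of any H3K4me3 region and/or any H3K27me3 region:
#' `K4+K27+` (bivalent), `K4+K27-`, `K4-K27+`, `K4-K27-`.
#'
#' @param genes A [gene_table()].
#' @param k4_regions,k27_regions Tibbles of intervals (`chrom`, `start`,
#'   `end`).
#' @param tss_halfwidth Promoter half-width in bp.
#' @return Gene grouping tibble (`gene_id`, `group`).
#' @export
classify_bivalent <- function(genes, k4_regions, k27_regions,
                              tss_halfwidth = 1000L) {
  genes <- gene_table(genes)
  win <- tibble(chrom = genes$chrom,
                start = genes$tss - tss_halfwidth,
                end = genes$tss + tss_halfwidth)
  hit <- function(regions) {
    regions <- as_tibble(regions)
    if (nrow(regions) == 0) return(rep(FALSE, nrow(genes)))
    purrr::pmap_lgl(win, function(chrom, start, end) {
      r <- regions[regions$chrom == chrom, ]
      any(r$start < end & start < r$end)
    })
  }
  k4 <- hit(k4_regions)
  k27 <- hit(k27_regions)
  tibble(
    gene_id = genes$gene_id,
    group = paste0(ifelse(k4, "K4+", "K4-"), ifelse(k27, "K27+", "K27-"))
  )
}

#' TSS/TTS-anchored metagene profile
#'
#' For each gene, signal is read in gene-relative bins of `bin` bp covering
#' `anchor - flank` to `anchor + flank`, reversed on minus-strand genes so
#' offsets always run 5' to 3'. A bin's value is the overlap-weighted mean of
#' the (at most two) track windows it straddles; bins extending beyond a
#' chromosome end are dropped from that offset's mean. Offsets label the
#' 5'-side bin edge relative to the anchor, so the two bins abutting the
#' anchor carry offsets `-bin` and `0`.
#'
#' @param track A `signal_track` (typically IP-IN) with window size `bin`.
#' @param genes A [gene_table()].
#' @param grouping Gene grouping tibble (`gene_id`, `group`) from one of the
#'   `partition_*()`/`classify_*()` functions; defaults to one group `all`.
#' @param anchor `"tss"` or `"tts"`.
#' @param flank Flank in bp on each side of the anchor (multiple of `bin`).
#' @param bin Bin width in bp; must equal the track window size.
#' @return A `metagene_profile` tibble: `group`, `offset`, `mean`, `n_genes`.
#' @export
metagene_profile <- function(track, genes, grouping = NULL,
                             anchor = c("tss", "tts"), flank = 5000L,
                             bin = 100L) {
  anchor <- match.arg(anchor)
  genes <- gene_table(genes)
  if (bin != track_window(track)) {
    abort("bin must equal the track window size")
  }
  if (flank %% bin != 0) abort("flank must be a multiple of bin")
  grouping <- grouping %||% tibble(gene_id = genes$gene_id, group = "all")
  sizes <- track_chrom_sizes(track)
  values <- split(track$value, track$chrom)
  offs <- seq(-flank, flank - bin, by = bin)
  a <- if (anchor == "tss") genes$tss else genes$tts
  # genomic start of the bin at offset o: strand + -> a + o ; strand - ->
  # half-open mirror [a - o - bin + 1, a - o + 1)
  per_gene <- purrr::map(seq_len(nrow(genes)), function(i) {
    ch <- genes$chrom[i]
    v <- values[[ch]]
    len <- sizes[[ch]]
    gstart <- if (genes$strand[i] == "+") a[i] + offs else a[i] - offs - bin + 1
    ok <- gstart >= 0 & (gstart + bin) <= len
    val <- rep(NA_real_, length(offs))
    if (any(ok)) {
      gs <- gstart[ok]
      k <- gs %/% bin
      phi <- gs %% bin
      v1 <- v[k + 1L]
      v2 <- v[pmin(k + 2L, length(v))]
      val[ok] <- ((bin - phi) * v1 + phi * v2) / bin
    }
    val
  })
  mat <- do.call(rbind, per_gene)
  prof <- dplyr::inner_join(grouping, tibble(gene_id = genes$gene_id,
                                             .row = seq_len(nrow(genes))),
                            by = "gene_id") |>
    dplyr::group_by(.data$group) |>
    dplyr::reframe(
      offset = offs,
      mean = colMeans(mat[.data$.row, , drop = FALSE], na.rm = TRUE),
      n_genes = length(.data$.row)
    )
  structure(prof, anchor = anchor,
            class = c("metagene_profile", class(tibble())))
}

#' Signal decay with distance from the TSS
#'
#' For each gene and distance `D`, collects the track-window value at
#' `TSS - D` and `TSS + D` (the window containing that position). Data points
#' whose queried position lies within `exclusion_radius` bp of any other
#' gene's TSS are dropped, so distal values are not contaminated by
#' neighbouring promoters.
#'
#' @param track A `signal_track`.
#' @param genes A [gene_table()].
#' @param distances Non-negative distances in bp.
#' @param exclusion_radius Exclusion radius around other TSSs in bp.
#' @return Tibble of retained points: `gene_id`, `distance` (signed),
#'   `value`.
#' @export
distal_decay <- function(track, genes, distances, exclusion_radius) {
  stopifnot(all(distances >= 0))
  genes <- gene_table(genes)
  w <- track_window(track)
  sizes <- track_chrom_sizes(track)
  values <- split(track$value, track$chrom)
  pts <- tidyr::expand_grid(i = seq_len(nrow(genes)),
                            distance = unique(c(-distances, distances))) |>
    dplyr::mutate(
      gene_id = genes$gene_id[.data$i],
      chrom = genes$chrom[.data$i],
      pos = genes$tss[.data$i] + .data$distance
    ) |>
    dplyr::filter(.data$pos >= 0, .data$pos < unname(sizes[.data$chrom]))
  near_other <- purrr::pmap_lgl(
    list(pts$i, pts$chrom, pts$pos),
    function(i, ch, pos) {
      other <- genes$tss[genes$chrom == ch & genes$gene_id != genes$gene_id[i]]
      length(other) > 0 && min(abs(other - pos)) <= exclusion_radius
    }
  )
  pts <- pts[!near_other, ]
  pts$value <- purrr::map2_dbl(pts$chrom, pts$pos, function(ch, pos) {
    values[[ch]][pos %/% w + 1L]
  })
  dplyr::select(pts, "gene_id", "distance", "value")
}
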