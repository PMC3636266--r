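#' Windowed signal tracks
#'
#' A signal track is a tibble with one row per fixed-width genomic window
#' (columns `chrom`, `start`, `value`; 0-based half-open window starts) plus
#' metadata: the window width, the normalization state (`"raw"`, `"per10M"`,
#' or `"ipin"`), the total mapped reads of the source library, and the
#' chromosome sizes. Windows tile each chromosome `[0, L)` in steps of the
#' window width; the last window of a chromosome may extend past `L` and is
#' truncated implicitly.
#'
#' @param df Tibble with columns `chrom`, `start`, `value`.
#' @param window Window width in bp.
#' @param norm Normalization state: `"raw"`, `"per10M"`, `"ipin"`, or `"gc"`.
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param total_reads Total mapped reads of the source library (`NA` for
#'   derived tracks such as GC%).
#' @return A `signal_track` tibble.
#' @export
new_signal_track <- function(df, window, norm, chrom_sizes,
                             total_reads = NA_real_) {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  df <- as_tibble(df)[, c("chrom", "start", "value")]
  expected <- sum(ceiling(chrom_sizes / window))
  if (nrow(df) != expected) {
    abort(sprintf(
      "signal track has %d windows; chromosome sizes at window %d require %d",
      nrow(df), window, expected
    ))
  }
  structure(
    df,
    class = c("signal_track", class(tibble())),
    window = as.integer(window),
    norm = norm,
    total_reads = total_reads,
    chrom_sizes = chrom_sizes
  )
}

#' @rdname new_signal_track
#' @param x A `signal_track`.
#' @export
track_window <- function(x) attr(x, "window")

#' @rdname new_signal_track
#' @export
track_norm <- function(x) attr(x, "norm")

#' @rdname new_signal_track
#' @export
track_total_reads <- function(x) attr(x, "total_reads")

#' @rdname new_signal_track
#' @export
track_chrom_sizes <- function(x) attr(x, "chrom_sizes")

# Rebuild a track with the same metadata but new values (same grid).
track_update <- function(x, value, norm = track_norm(x),
                         total_reads = track_total_reads(x)) {
  new_signal_track(
    tibble(chrom = x$chrom, start = x$start, value = value),
    window = track_window(x), norm = norm,
    chrom_sizes = track_chrom_sizes(x), total_reads = total_reads
  )
}

# Dense window grid for a chromosome set.
window_grid <- function(chrom_sizes, w) {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  purrr::map2_dfr(names(chrom_sizes), chrom_sizes, function(ch, len) {
    tibble(chrom = ch, start = seq(0L, by = w, length.out = ceiling(len / w)))
  })
}

#' Count fragment midpoints in tiling windows
#'
#' Each read contributes one count to the window containing its fragment
#' midpoint. Windows tile `[0, L)` in non-overlapping steps of `w` bp.
#'
#' @param reads Tibble of reads with a `chrom` column and either a `midpoint`
#'   column or `start`/`end` fragment intervals (0-based half-open) from which
#'   midpoints are taken as `floor((start + end) / 2)`.
#' @param chrom_sizes Named vector (or chrom/length tibble) of chromosome
#'   lengths.
#' @param w Window width in bp (default 100).
#' @return A raw-count `signal_track`; its `total_reads` attribute is the
#'   number of reads counted.
#' @export
window_counts <- function(reads, chrom_sizes, w = 100L) {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  reads <- as_tibble(reads)
  if (!"midpoint" %in% names(reads)) {
    check_intervals(reads, chrom_sizes, what = "read interval")
    reads$midpoint <- floor((reads$start + reads$end) / 2)
  }
  bad <- !(reads$chrom %in% names(chrom_sizes)) |
    reads$midpoint < 0 | reads$midpoint >= unname(chrom_sizes[reads$chrom])
  if (any(bad, na.rm = TRUE) || anyNA(bad)) {
    i <- which(bad | is.na(bad))[1]
    abort(sprintf(
      "read %d has midpoint %s:%s outside chromosome bounds",
      i, reads$chrom[i], format(reads$midpoint[i])
    ))
  }
  grid <- window_grid(chrom_sizes, w)
  key <- paste0(grid$chrom, ":", grid$start)
  hit <- paste0(reads$chrom, ":", floor(reads$midpoint / w) * w)
  counts <- tabulate(match(hit, key), nbins = nrow(grid))
  new_signal_track(
    tibble(chrom = grid$chrom, start = grid$start, value = as.numeric(counts)),
    window = w, norm = "raw", chrom_sizes = chrom_sizes,
    total_reads = nrow(reads)
  )
}

#' Normalize a raw track to reads per 10 million mapped
#'
#' Scales every window value by `1e7 / total_mapped` so libraries of
#' different depths are comparable.
#'
#' @param track Raw-count `signal_track`.
#' @param total_mapped Total mapped reads of the library; defaults to the
#'   track's own `total_reads` attribute.
#' @return A `signal_track` with normalization `"per10M"`.
#' @export
normalize_per_10m <- function(track, total_mapped = track_total_reads(track)) {
  if (is.na(total_mapped) || total_mapped <= 0) {
    abort("total_mapped must be a positive count")
  }
  track_update(track, track$value * 1e7 / total_mapped, norm = "per10M",
               total_reads = total_mapped)
}

#' IP minus input difference track
#'
#' Window-wise subtraction of the normalized input-control track from the
#' normalized ChIP track. Both tracks must be per-10M normalized, on the same
#' chromosomes and window grid.
#'
#' @param chip,input Per-10M `signal_track`s.
#' @return A `signal_track` with normalization `"ipin"`; values may be
#'   negative.
#' @export
ipin <- function(chip, input) {
  if (track_window(chip) != track_window(input)) {
    abort("chip and input tracks have different window sizes")
  }
  if (!identical(track_chrom_sizes(chip), track_chrom_sizes(input))) {
    abort("chip and input tracks have different chromosome sets")
  }
  if (track_norm(chip) != "per10M" || track_norm(input) != "per10M") {
    abort("ipin() expects per-10M normalized tracks; see normalize_per_10m()")
  }
  track_update(chip, chip$value - input$value, norm = "ipin")
}

#' GC% track from genome sequence
#'
#' Per tiling window, `100 * (G + C) / (A + C + G + T)`; `N` bases are
#' excluded from the denominator and windows that are entirely `N` get `NA`.
#'
#' @param genome A [Biostrings::DNAStringSet] of chromosome sequences.
#' @param w Window width in bp.
#' @return A `signal_track` with normalization `"gc"`.
#' @export
gc_track <- function(genome, w = 100L) {
  chrom_sizes <- setNames(Biostrings::width(genome), names(genome))
  vals <- purrr::map(seq_along(genome), function(i) {
    len <- chrom_sizes[i]
    starts <- seq(1L, len, by = w)
    ends <- pmin(starts + w - 1L, len)
    v <- Biostrings::Views(genome[[i]], start = starts, end = ends)
    counts <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    acgt <- rowSums(counts)
    gc <- counts[, "G"] + counts[, "C"]
    ifelse(acgt == 0, NA_real_, 100 * gc / acgt)
  })
  grid <- window_grid(chrom_sizes, w)
  new_signal_track(
    tibble(chrom = grid$chrom, start = grid$start, value = unlist(vals)),
    window = w, norm = "gc", chrom_sizes = chrom_sizes
  )
}

#' Rebin a track to a coarser window by summation
#'
#' Values are summed over consecutive groups of `W / w` windows per
#' chromosome; the track total is preserved exactly. `NA` windows propagate
#' `NA` unless all constituents are `NA`-free.
#'
#' @param track A `signal_track` at base window `w`.
#' @param W Target window width; must be a multiple of `w`.
#' @return A `signal_track` at window `W` with the same normalization state.
#' @export
rebin <- function(track, W) {
  w <- track_window(track)
  if (W %% w != 0) abort(sprintf("W = %d is not a multiple of w = %d", W, w))
  if (W == w) return(track)
  df <- tibble(chrom = track$chrom,
               start = floor(track$start / W) * W,
               value = track$value) |>
    dplyr::group_by(.data$chrom, .data$start) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop") |>
    dplyr::arrange(match(.data$chrom, names(track_chrom_sizes(track))),
                   .data$start)
  new_signal_track(df, window = W, norm = track_norm(track),
                   chrom_sizes = track_chrom_sizes(track),
                   total_reads = track_total_reads(track))
}

#' Mean track signal over regions
#'
#' For each region, the mean of overlapping window values weighted by the
#' overlap length in bp.
#'
#' @param track A `signal_track`.
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @return The input regions with a `signal` column appended.
#' @export
region_signal <- function(track, regions) {
  regions <- as_tibble(regions)
  if (nrow(regions) == 0L) {
    return(dplyr::mutate(regions, signal = numeric(0)))
  }
  check_intervals(regions, track_chrom_sizes(track), what = "region")
  w <- track_window(track)
  values <- split(track$value, track$chrom)
  sig <- purrr::pmap_dbl(
    list(regions$chrom, regions$start, regions$end),
    function(ch, s, e) {
      v <- values[[ch]]
      idx <- seq(floor(s / w), floor((e - 1) / w))
      ws <- idx * w
      ov <- pmin(e, ws + w) - pmax(s, ws)
      vv <- v[idx + 1L]
      keep <- !is.na(vv)
      if (!any(keep)) return(NA_real_)
      sum(vv[keep] * ov[keep]) / sum(ov[keep])
    }
  )
  dplyr::mutate(regions, signal = sig)
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("# signal_track: %d windows of %d bp, %s normalization\n",
              nrow(x), track_window(x), track_norm(x)))
  NextMethod()
}
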