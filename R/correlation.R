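#' Genome-wide correlation between two signal tracks
#'
#' Both tracks are rebinned to `W` bp by summation, windows with a missing
#' value in either track are dropped pairwise, and the Pearson correlation is
#' computed over all remaining windows pooled across chromosomes, with a
#' two-sided p-value from the t transform.
#'
#' @param a,b `signal_track`s sharing chromosomes and base window size.
#' @param W Correlation window in bp (multiple of the base window;
#'   default 1000).
#' @param drop_zero Drop windows where both tracks are zero before
#'   correlating (default `FALSE`: zero-signal windows are kept).
#' @param label_a,label_b Track labels for the output.
#' @return One-row tibble: `track_a`, `track_b`, `scope`, `n`, `r`, `p`.
#'   `r` is `NA` (with a message) when either vector has zero variance.
#' @export
genome_correlation <- function(a, b, W = 1000L, drop_zero = FALSE,
                               label_a = "a", label_b = "b") {
  paired <- pair_windows(a, b, W, drop_zero)
  cor_row(paired$x, paired$y, "genome", label_a, label_b)
}

#' Per-chromosome correlation between two signal tracks
#'
#' @inheritParams genome_correlation
#' @return Tibble with one row per chromosome (scope = chromosome name).
#' @export
per_chromosome_correlation <- function(a, b, W = 1000L, drop_zero = FALSE,
                                       label_a = "a", label_b = "b") {
  paired <- pair_windows(a, b, W, drop_zero)
  split(paired, paired$chrom) |>
    purrr::imap(function(d, ch) cor_row(d$x, d$y, ch, label_a, label_b)) |>
    dplyr::bind_rows()
}

pair_windows <- function(a, b, W, drop_zero) {
  if (track_window(a) != track_window(b)) {
    abort("tracks have different base window sizes")
  }
  if (!identical(names(track_chrom_sizes(a)), names(track_chrom_sizes(b)))) {
    abort("tracks have different chromosome sets")
  }
  ra <- rebin(a, W)
  rb <- rebin(b, W)
  d <- tibble(chrom = ra$chrom, x = ra$value, y = rb$value) |>
    dplyr::filter(!is.na(.data$x), !is.na(.data$y))
  if (drop_zero) d <- dplyr::filter(d, .data$x != 0 | .data$y != 0)
  d
}

cor_row <- function(x, y, scope, label_a, label_b) {
  n <- length(x)
  if (n < 3) abort(sprintf("only %d paired windows in scope '%s' (need >= 3)",
                           n, scope))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    message(sprintf("zero variance in scope '%s': R undefined", scope))
    return(tibble(track_a = label_a, track_b = label_b, scope = scope,
                  n = n, r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(track_a = label_a, track_b = label_b, scope = scope, n = n,
         r = unname(ct$estimate), p = ct$p.value)
}
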