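#' Apparent nucleosome repeat length at one digestion timepoint
#'
#' Ordinary-least-squares slope of polynucleosome band size (bp) on band
#' number for one MNase timepoint. The intercept is left free: end-trimming
#' by the nuclease shifts all band sizes by a constant, which moves the
#' intercept but not the slope.
#'
#' @param obs Tibble of ladder observations for one timepoint (`band_n`,
#'   `size_bp`).
#' @return The slope in bp per nucleosome (the apparent NRL at this
#'   timepoint).
#' @export
nrl_at_timepoint <- function(obs) {
  obs <- as_tibble(obs)
  if (length(unique(obs$band_n)) < 2) {
    abort("need at least 2 distinct band numbers to fit a slope")
  }
  unname(coef(lm(size_bp ~ band_n, data = obs))["band_n"])
}

#' Per-timepoint apparent NRLs from a ladder table
#'
#' @param obs Ladder observations (`time_min`, `band_n`, `size_bp`).
#' @return Tibble with `time_min` and `nrl_bp` (apparent NRL).
#' @export
nrl_by_timepoint <- function(obs) {
  as_tibble(obs) |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(nrl_bp = nrl_at_timepoint(dplyr::pick(dplyr::everything())),
                     .groups = "drop")
}

#' Extrapolate the NRL to zero digestion time
#'
#' OLS regression of the per-timepoint apparent NRL (slope) on digestion
#' time; the intercept is the zero-time nucleosome repeat length, reported
#' with its standard error.
#'
#' @param x Either a tibble of per-timepoint slopes (`time_min`, `nrl_bp`)
#'   from [nrl_by_timepoint()], or raw ladder observations (`time_min`,
#'   `band_n`, `size_bp`), which are reduced to slopes first.
#' @return An `nrl_fit` object; use [tidy()]/[glance()] or `$nrl0`.
#' @export
nrl_extrapolate <- function(x) {
  x <- as_tibble(x)
  if ("band_n" %in% names(x)) x <- nrl_by_timepoint(x)
  if (nrow(x) < 2) {
    abort(paste("need >= 2 timepoints to extrapolate;",
                "use nrl_at_timepoint() for a single digest"))
  }
  fit <- lm(nrl_bp ~ time_min, data = x)
  sm <- summary(fit)$coefficients
  structure(
    list(nrl0 = unname(coef(fit)[1]), se = sm["(Intercept)", "Std. Error"],
         rate = -unname(coef(fit)[2]), fit = fit, slopes = x),
    class = "nrl_fit"
  )
}

#' @export
print.nrl_fit <- function(x, ...) {
  cat(sprintf("NRL at time 0: %.1f bp (SE %.2f); shortening %.2f bp/min\n",
              x$nrl0, x$se, x$rate))
  invisible(x)
}

#' @rdname nrl_extrapolate
#' @param ... Unused.
#' @method tidy nrl_fit
#' @export
tidy.nrl_fit <- function(x, ...) {
  tibble(term = c("nrl0_bp", "shortening_bp_per_min"),
         estimate = c(x$nrl0, x$rate),
         std.error = c(x$se, summary(x$fit)$coefficients["time_min",
                                                         "Std. Error"]))
}

#' @rdname nrl_extrapolate
#' @method glance nrl_fit
#' @export
glance.nrl_fit <- function(x, ...) {
  tibble(nrl0_bp = x$nrl0, se_bp = x$se, rate_bp_per_min = x$rate,
         n_timepoints = nrow(x$slopes),
         r.squared = summary(x$fit)$r.squared)
}

#' Linker histones per nucleosome from chromatographic peak areas
#'
#' Peak areas (A214) are first adjusted by the number of peptide bonds in
#' each protein (A214 absorbance is proportional to peptide-bond count); the
#' H1-per-nucleosome ratio is the sum of adjusted H1 areas divided by half
#' the adjusted H2B area (each nucleosome carries two H2B copies).
#'
#' @param h1_areas,h1_bonds Peak areas and peptide-bond counts per H1
#'   variant (equal-length vectors; empty for no H1).
#' @param h2b_area,h2b_bonds H2B peak area (> 0) and peptide-bond count.
#' @return H1 molecules per nucleosome.
#' @export
h1_per_nucleosome <- function(h1_areas, h1_bonds, h2b_area, h2b_bonds) {
  stopifnot(length(h1_areas) == length(h1_bonds),
            all(h1_areas >= 0), all(h1_bonds >= 1), h2b_bonds >= 1)
  if (h2b_area <= 0) abort("H2B peak area must be positive")
  sum(h1_areas / h1_bonds) / ((h2b_area / h2b_bonds) / 2)
}

#' Relative expression from qRT-PCR signals
#'
#' Mock reverse-transcribed signals (RT-) are subtracted from reverse
#' transcribed signals (RT+) for both target and housekeeping reference, and
#' the adjusted target is normalized by the adjusted reference. Signals are
#' linear quantities (post standard-curve or 2^-Ct transform); a negative
#' adjusted target is clamped to 0 with a warning.
#'
#' @param target_rt_plus,target_rt_minus Target RT+ and RT- signals.
#' @param ref_rt_plus,ref_rt_minus Reference (housekeeping) RT+ and RT-
#'   signals; the adjusted reference must be positive.
#' @return Relative expression units (vectorized over the target).
#' @export
relative_expression <- function(target_rt_plus, target_rt_minus,
                                ref_rt_plus, ref_rt_minus) {
  ref <- ref_rt_plus - ref_rt_minus
  if (any(ref <= 0)) abort("adjusted reference signal must be positive")
  adj <- target_rt_plus - target_rt_minus
  if (any(adj < 0)) {
    warn(sprintf("%d target signal(s) below mock-RT background; clamped to 0",
                 sum(adj < 0)))
    adj <- pmax(adj, 0)
  }
  adj / ref
}

#' qChIP relative enrichment over IgG
#'
#' @param chip_signal ChIP qPCR signal.
#' @param igg_signal IgG (mock antibody) qPCR signal; must be positive.
#' @return `chip_signal / igg_signal` (vectorized).
#' @export
qchip_relative_enrichment <- function(chip_signal, igg_signal) {
  if (any(igg_signal <= 0)) abort("IgG signal must be positive")
  chip_signal / igg_signal
}

#' Percent methylated CpG from bisulfite clone calls
#'
#' `100 * methylated calls / total scored calls` over a per-clone, per-CpG
#' binary call matrix; missing (unscored) calls are excluded from the
#' denominator.
#'
#' @param calls Matrix or data frame of calls, clones in rows and CpG sites
#'   in columns: 1 = methylated, 0 = unmethylated, `NA` = not scored.
#' @return Percent methylated CpG for the amplicon.
#' @export
percent_methylated <- function(calls) {
  m <- as.matrix(calls)
  if (length(m) == 0) abort("empty call matrix")
  scored <- sum(!is.na(m))
  if (scored == 0) abort("no scored CpG calls")
  100 * sum(m == 1, na.rm = TRUE) / scored
}
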