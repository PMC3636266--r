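#' Specify a simulated MNase digestion time course
#'
#' Micrococcal nuclease preferentially cuts linker DNA; electrophoresis of a
#' partial digest gives a ladder of mono-, di-, tri-nucleosome bands. Because
#' the enzyme trims nucleosomal ends as digestion proceeds, the apparent
#' repeat length (band-size slope) shrinks with digestion time; the true
#' nucleosome repeat length is recovered by extrapolating the per-timepoint
#' slopes back to time zero. The simulator draws band sizes
#' `S(n, t) = n * (NRL0 - rate * t) + intercept + eps`,
#' `eps ~ Normal(0, noise_sd^2)` independently per band.
#'
#' @param nrl0 True zero-time nucleosome repeat length in bp (> 0).
#' @param rate Apparent shortening rate in bp per minute of digestion.
#' @param timepoints Digestion timepoints in minutes; strictly positive and
#'   increasing.
#' @param n_bands Number of ladder bands per timepoint (>= 2).
#' @param intercept Constant band-size offset in bp (end-trimming at the gel
#'   calibration level).
#' @param noise_sd Gaussian band-size measurement noise SD in bp.
#' @return A `ladder_spec` list.
#' @export
ladder_spec <- function(nrl0, rate = 1, timepoints = c(2.5, 5, 10),
                        n_bands = 8L, intercept = 0, noise_sd = 5) {
  stopifnot(nrl0 > 0, n_bands >= 2, noise_sd >= 0,
            all(timepoints > 0), !is.unsorted(timepoints, strictly = TRUE))
  if (nrl0 - rate * max(timepoints) <= 0) {
    abort("nrl0 - rate * max(timepoints) <= 0: digestion model collapses")
  }
  structure(list(nrl0 = nrl0, rate = rate, timepoints = timepoints,
                 n_bands = as.integer(n_bands), intercept = intercept,
                 noise_sd = noise_sd),
            class = "ladder_spec")
}

#' Simulate MNase ladder band sizes
#'
#' @param spec A [ladder_spec()].
#' @param seed Integer seed.
#' @return Tibble of ladder observations: `time_min`, `band_n`, `size_bp`.
#' @export
simulate_mnase_ladder <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "ladder_spec"))
  with_seed(seed, {
    obs <- tidyr::expand_grid(time_min = spec$timepoints,
                              band_n = seq_len(spec$n_bands))
    obs$size_bp <- obs$band_n * (spec$nrl0 - spec$rate * obs$time_min) +
      spec$intercept + rnorm(nrow(obs), sd = spec$noise_sd)
    obs
  })
}
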