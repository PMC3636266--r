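#' Repeat consensus library
#'
#' A repeat library holds named consensus sequences with class labels (the
#' desk-scale analogue of a RepBase-style library). Entries sharing a class
#' label are aggregated at the class level by [percent_mapped()] and
#' [repeat_enrichment_table()].
#'
#' @param entries Tibble with `name` (unique), `class`, `consensus`
#'   (A/C/G/T/N).
#' @return A `repeat_library` tibble.
#' @export
repeat_library <- function(entries) {
  entries <- as_tibble(entries)[, c("name", "class", "consensus")]
  entries$consensus <- toupper(entries$consensus)
  if (anyDuplicated(entries$name)) abort("repeat entry names must be unique")
  if (any(grepl("[^ACGTN]", entries$consensus))) {
    abort("consensus sequences must be over {A,C,G,T,N}")
  }
  structure(entries, class = c("repeat_library", class(tibble())))
}

#' Read a repeat library from FASTA
#'
#' Headers are `name|class`; a header without `|` gets its name as class.
#'
#' @param path FASTA file path.
#' @return A [repeat_library()].
#' @export
read_repeat_library <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  hdr <- stringr::str_split_fixed(names(seqs), stringr::fixed("|"), 2)
  cls <- ifelse(hdr[, 2] == "", hdr[, 1], hdr[, 2])
  repeat_library(tibble(name = hdr[, 1], class = cls,
                        consensus = as.character(seqs)))
}

#' Assign reads to repeat consensus entries by seed matching
#'
#' The first `seed_len` bases of each read are matched against every library
#' entry with up to `max_mismatch` mismatches. Each consensus is doubled (two
#' concatenated copies) before scanning so seeds spanning tandem-monomer
#' junctions are found, and both strands are scanned (reverse complement of
#' the doubled consensus). A read hitting two or more entries is a multiread
#' and is assigned uniformly at random among the tied entries with the seeded
#' generator; a read hitting none is unassigned. `N` never counts as a match.
#'
#' @param reads Tibble with `read_id` and `seq` columns, or a character vector
#'   of read sequences.
#' @param library A [repeat_library()].
#' @param seed_len Seed length in bp (default 35); every read must be at least
#'   this long.
#' @param max_mismatch Maximum mismatches allowed in the seed (default 2).
#' @param rng_seed Integer seed for the random multiread placement.
#' @return Tibble with `read_id`, `repeat_name` (`NA` if unassigned), `class`,
#'   `n_candidates` (number of entries the seed hit).
#' @export
assign_reads_to_repeats <- function(reads, library, seed_len = 35L,
                                    max_mismatch = 2L, rng_seed = 1L) {
  if (is.character(reads)) {
    reads <- tibble(read_id = sprintf("read_%07d", seq_along(reads)),
                    seq = reads)
  }
  stopifnot(inherits(library, "repeat_library"))
  seqs <- toupper(reads$seq)
  if (any(nchar(seqs) < seed_len)) {
    abort(sprintf("all reads must be at least seed_len = %d bases", seed_len))
  }
  if (any(nchar(library$consensus) < seed_len)) {
    abort("library consensus sequences must be at least seed_len long")
  }
  seeds <- substr(seqs, 1L, seed_len)
  doubled <- strrep(library$consensus, 2L)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(doubled))
  )
  hits <- seed_hits_cpp(seeds, c(doubled, rc), as.integer(max_mismatch))
  n_entry <- nrow(library)
  with_seed(rng_seed, {
    assigned <- purrr::map_int(hits, function(h) {
      if (length(h) == 0L) return(NA_integer_)
      ent <- unique((h - 1L) %% n_entry + 1L)
      if (length(ent) == 1L) ent else ent[sample.int(length(ent), 1L)]
    })
    n_cand <- purrr::map_int(hits, function(h) {
      length(unique((h - 1L) %% n_entry + 1L))
    })
    tibble(
      read_id = reads$read_id,
      repeat_name = library$name[assigned],
      class = library$class[assigned],
      n_candidates = n_cand
    )
  })
}

#' Percent of library reads mapped per repeat class
#'
#' `100 * reads_in_class / total_reads`; entries sharing a class label are
#' aggregated.
#'
#' @param assignment Output of [assign_reads_to_repeats()].
#' @param total_reads Total reads in the sequencing library (>= number
#'   assigned); the denominator is the whole library, not just assigned reads.
#' @param library Optional [repeat_library()]; when given, classes with zero
#'   assigned reads are included at 0%.
#' @return Tibble with `class`, `reads_in_class`, `percent`.
#' @export
percent_mapped <- function(assignment, total_reads, library = NULL) {
  if (total_reads <= 0) abort("total_reads must be positive")
  n_assigned <- sum(!is.na(assignment$repeat_name))
  if (total_reads < n_assigned) {
    abort("total_reads is smaller than the number of assigned reads")
  }
  counts <- assignment |>
    dplyr::filter(!is.na(.data$class)) |>
    dplyr::count(.data$class, name = "reads_in_class")
  if (!is.null(library)) {
    counts <- tibble(class = unique(library$class)) |>
      dplyr::left_join(counts, by = "class") |>
      dplyr::mutate(reads_in_class = dplyr::coalesce(.data$reads_in_class, 0L))
  }
  dplyr::mutate(counts, percent = 100 * .data$reads_in_class / total_reads) |>
    dplyr::arrange(.data$class)
}

#' Fold enrichment of a repeat class in ChIP over input
#'
#' The ratio of the percent of ChIP-library reads mapped to the class to the
#' percent of input-library reads mapped to it. A class with zero input
#' percent but nonzero ChIP percent is undefined and reported as `NA` with a
#' warning (never silently infinite).
#'
#' @param chip_pct,input_pct Percent-mapped values (vectorized).
#' @return Numeric fold enrichment.
#' @export
fold_enrichment <- function(chip_pct, input_pct) {
  stopifnot(length(chip_pct) == length(input_pct))
  undef <- input_pct == 0 & chip_pct > 0
  if (any(undef, na.rm = TRUE)) {
    warn(sprintf("%d class(es) have zero input percent; fold is undefined (NA)",
                 sum(undef, na.rm = TRUE)))
  }
  out <- chip_pct / input_pct
  out[undef] <- NA_real_
  out[input_pct == 0 & chip_pct == 0] <- NaN
  out
}

#' Two-sided Fisher's exact test for repeat-class enrichment
#'
#' Tests the 2x2 table of reads in/out of a repeat class in the ChIP library
#' against the input library.
#'
#' @param chip_in,chip_total,input_in,input_total Read counts (vectorized;
#'   `in <= total`, all non-negative).
#' @return Two-sided exact p-value(s).
#' @export
repeat_exact_test <- function(chip_in, chip_total, input_in, input_total) {
  if (any(c(chip_in, chip_total, input_in, input_total) < 0)) {
    abort("counts must be non-negative")
  }
  if (any(chip_in > chip_total) || any(input_in > input_total)) {
    abort("in-class counts cannot exceed library totals")
  }
  purrr::pmap_dbl(
    list(chip_in, chip_total, input_in, input_total),
    function(ci, ct, ii, it) {
      m <- matrix(c(ci, ct - ci, ii, it - ii), nrow = 2, byrow = TRUE)
      stats::fisher.test(m)$p.value
    }
  )
}

#' Per-class repeat enrichment table
#'
#' Combines ChIP and input assignments into the per-class summary: read
#' counts, percent mapped, fold enrichment over input, and the two-sided
#' exact-test p-value.
#'
#' @param chip_assignment,input_assignment Outputs of
#'   [assign_reads_to_repeats()] for the ChIP and input libraries.
#' @param chip_total,input_total Total reads in each library.
#' @param library Optional [repeat_library()] to include zero-count classes.
#' @return A `repeat_enrichment` tibble: `class`, `chip_in`, `chip_total`,
#'   `input_in`, `input_total`, `chip_pct`, `input_pct`, `fold`, `p_value`.
#' @export
repeat_enrichment_table <- function(chip_assignment, input_assignment,
                                    chip_total, input_total, library = NULL) {
  chip <- percent_mapped(chip_assignment, chip_total, library)
  input <- percent_mapped(input_assignment, input_total, library)
  tab <- dplyr::full_join(
    dplyr::rename(chip, chip_in = "reads_in_class", chip_pct = "percent"),
    dplyr::rename(input, input_in = "reads_in_class", input_pct = "percent"),
    by = "class"
  ) |>
    dplyr::mutate(
      chip_in = dplyr::coalesce(.data$chip_in, 0L),
      input_in = dplyr::coalesce(.data$input_in, 0L),
      chip_pct = dplyr::coalesce(.data$chip_pct, 0),
      input_pct = dplyr::coalesce(.data$input_pct, 0),
      chip_total = chip_total,
      input_total = input_total,
      fold = fold_enrichment(.data$chip_pct, .data$input_pct),
      p_value = repeat_exact_test(.data$chip_in, chip_total,
                                  .data$input_in, input_total)
    ) |>
    dplyr::select("class", "chip_in", "chip_total", "input_in", "input_total",
                  "chip_pct", "input_pct", "fold", "p_value")
  structure(tab, class = c("repeat_enrichment", class(tibble())))
}
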