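#' Specify a synthetic mini-genome
#'
#' A genome spec declares chromosome lengths, tandem repeat arrays (monomer
#' sequence, copy number, per-base divergence), gene intervals with expression
#' values, and the background base composition. It is the blueprint consumed
#' by [build_genome()].
#'
#' @param chrom_sizes Named vector of chromosome lengths in bp.
#' @param repeats Tibble of repeat array specs: `name`, `class`, `chrom`,
#'   `start`, `monomer` (sequence), `copies` (>= 1), `divergence` (per-base
#'   substitution rate in `[0, 1)`).
#' @param genes Tibble of gene specs: `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`+`/`-`), `expression` (>= 0).
#' @param at_fraction Background AT fraction in `[0, 1]` (mouse pericentromeric
#'   satellite DNA is AT-rich; the genome-wide default 0.58 matches bulk
#'   mammalian composition).
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(chrom_sizes, repeats = NULL, genes = NULL,
                        at_fraction = 0.58) {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  repeats <- if (is.null(repeats)) {
    tibble(name = character(), class = character(), chrom = character(),
           start = integer(), monomer = character(), copies = integer(),
           divergence = double())
  } else {
    as_tibble(repeats)
  }
  genes <- if (is.null(genes)) {
    tibble(gene_id = character(), chrom = character(), start = integer(),
           end = integer(), strand = character(), expression = double())
  } else {
    as_tibble(genes)
  }
  if (at_fraction < 0 || at_fraction > 1) abort("at_fraction must be in [0, 1]")
  if (nrow(repeats) > 0) {
    stopifnot(all(repeats$copies >= 1),
              all(repeats$divergence >= 0 & repeats$divergence < 1))
    repeats$monomer <- toupper(repeats$monomer)
    repeats$end <- repeats$start + nchar(repeats$monomer) * repeats$copies
    check_intervals(repeats, chrom_sizes, what = "repeat array")
  } else {
    repeats$end <- integer(0)
  }
  if (nrow(genes) > 0) {
    stopifnot(all(genes$strand %in% c("+", "-")), all(genes$expression >= 0))
    check_intervals(genes, chrom_sizes, what = "gene")
  }
  placed <- dplyr::bind_rows(
    dplyr::select(repeats, "chrom", "start", "end") |>
      dplyr::mutate(label = repeats$name),
    dplyr::select(genes, "chrom", "start", "end") |>
      dplyr::mutate(label = genes$gene_id)
  )
  if (nrow(placed) > 1) {
    placed <- dplyr::arrange(placed, .data$chrom, .data$start)
    clash <- placed |>
      dplyr::group_by(.data$chrom) |>
      dplyr::filter(dplyr::lead(.data$start) < .data$end) |>
      dplyr::ungroup()
    if (nrow(clash) > 0) {
      abort(paste0(
        "placed features overlap: ",
        paste(sprintf("%s@%s:[%d,%d)", clash$label, clash$chrom,
                      clash$start, clash$end), collapse = ", ")
      ))
    }
  }
  structure(list(chrom_sizes = chrom_sizes, repeats = repeats, genes = genes,
                 at_fraction = at_fraction),
            class = "genome_spec")
}

# Mutate each base of `seq_chars` independently at rate `rate`, drawing the
# replacement uniformly from the other three bases.
mutate_bases <- function(seq_chars, rate) {
  if (rate == 0) return(seq_chars)
  hit <- runif(length(seq_chars)) < rate
  if (!any(hit)) return(seq_chars)
  bases <- c("A", "C", "G", "T")
  repl <- vapply(seq_chars[hit], function(b) {
    sample(setdiff(bases, b), 1L)
  }, character(1))
  seq_chars[hit] <- repl
  seq_chars
}

#' Build a synthetic genome from a spec
#'
#' Background sequence is drawn i.i.d. at the spec's AT fraction; each repeat
#' array is laid down as `copies` tandem copies of its monomer with every base
#' independently substituted at the divergence rate, emulating the sequence
#' heterogeneity of real satellite arrays. Genes annotate intervals of
#' background sequence.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed; the build is a pure function of `(spec, seed)`.
#' @return A list with `genome` (a [Biostrings::DNAStringSet]) and `features`
#'   (tibble of every placed feature: `chrom`, `start`, `end`, `strand`,
#'   `class`, `name`, `expression`).
#' @export
build_genome <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(seed, {
    at <- spec$at_fraction
    probs <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
    seqs <- purrr::imap(as.list(spec$chrom_sizes), function(len, ch) {
      chars <- sample(names(probs), len, replace = TRUE, prob = probs)
      reps <- dplyr::filter(spec$repeats, .data$chrom == ch)
      if (nrow(reps) > 0) {
        for (i in seq_len(nrow(reps))) {
          mono <- strsplit(reps$monomer[i], "")[[1]]
          arr <- mutate_bases(rep.int(mono, reps$copies[i]),
                              reps$divergence[i])
          chars[(reps$start[i] + 1L):reps$end[i]] <- arr
        }
      }
      paste(chars, collapse = "")
    })
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- names(spec$chrom_sizes)
    features <- dplyr::bind_rows(
      if (nrow(spec$repeats) > 0) {
        tibble(chrom = spec$repeats$chrom, start = spec$repeats$start,
               end = spec$repeats$end, strand = "+",
               class = spec$repeats$class, name = spec$repeats$name,
               expression = NA_real_)
      },
      if (nrow(spec$genes) > 0) {
        tibble(chrom = spec$genes$chrom, start = spec$genes$start,
               end = spec$genes$end, strand = spec$genes$strand,
               class = "gene", name = spec$genes$gene_id,
               expression = spec$genes$expression)
      }
    )
    if (is.null(features) || nrow(features) == 0) {
      features <- tibble(chrom = character(), start = integer(),
                         end = integer(), strand = character(),
                         class = character(), name = character(),
                         expression = double())
    }
    list(genome = genome, features = dplyr::arrange(features, .data$chrom,
                                                    .data$start))
  })
}

#' Derive a gene table from a feature annotation
#'
#' Converts `class == "gene"` features into the gene-table layout used by the
#' metagene module: TSS at the 5' end, TTS at the 3' end (both as 0-based base
#' coordinates; on the minus strand the TSS is the larger coordinate).
#'
#' @param features Feature tibble from [build_genome()].
#' @return Tibble with `gene_id`, `chrom`, `strand`, `tss`, `tts`,
#'   `expression`.
#' @export
genes_from_features <- function(features) {
  g <- dplyr::filter(as_tibble(features), .data$class == "gene")
  tibble(
    gene_id = g$name,
    chrom = g$chrom,
    strand = g$strand,
    tss = ifelse(g$strand == "+", g$start, g$end - 1L),
    tts = ifelse(g$strand == "+", g$end - 1L, g$start),
    expression = g$expression
  )
}
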