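#' Read and write the pipeline's plain-text formats
#'
#' All genomic coordinates are 0-based half-open, matching BED natively.
#' `write_bed6()` emits chrom/start/end/name/score/strand; `write_bedgraph()`
#' emits a 4-column bedGraph from a signal track, skipping `NA` windows;
#' `write_reads_fastq()` writes simulated reads with a constant quality
#' string; `read_genes_tsv()` reads the gene table layout (`gene_id`,
#' `chrom`, `strand`, `tss`, `tts`, `expression`).
#'
#' @param df Tibble of intervals with at least `chrom`, `start`, `end`;
#'   optional `name`, `score`, `strand`.
#' @param path Output file path.
#' @return The path, invisibly (writers); a tibble (readers).
#' @name satchrom-io
NULL

#' @rdname satchrom-io
#' @export
write_bed6 <- function(df, path) {
  df <- as_tibble(df)
  out <- tibble(
    chrom = df$chrom,
    start = df$start,
    end = df$end,
    name = df$name %||% sprintf("region_%d", seq_len(nrow(df))),
    score = df$score %||% 0,
    strand = df$strand %||% "."
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname satchrom-io
#' @export
read_bed6 <- function(path) {
  readr::read_tsv(path,
                  col_names = c("chrom", "start", "end", "name", "score",
                                "strand"),
                  col_types = "ciicdc", progress = FALSE)
}

#' @rdname satchrom-io
#' @param track A `signal_track`.
#' @export
write_bedgraph <- function(track, path) {
  w <- track_window(track)
  sizes <- track_chrom_sizes(track)
  out <- tibble(
    chrom = track$chrom,
    start = track$start,
    end = pmin(track$start + w, unname(sizes[track$chrom])),
    value = track$value
  ) |> dplyr::filter(!is.na(.data$value))
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname satchrom-io
#' @param reads Read tibble from [simulate_library()].
#' @export
write_reads_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$seq))
  readr::write_lines(
    as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+", qual)),
    path
  )
  invisible(path)
}

#' @rdname satchrom-io
#' @export
read_reads_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = sub(" .*", "", names(seqs)), seq = as.character(seqs))
}

#' @rdname satchrom-io
#' @export
read_genes_tsv <- function(path) {
  gene_table(readr::read_tsv(path, col_types = readr::cols(), progress = FALSE))
}

#' @rdname satchrom-io
#' @param genome A [Biostrings::DNAStringSet].
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
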