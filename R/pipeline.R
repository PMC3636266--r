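#' Demo pipeline configuration
#'
#' Builds the bundled demo configuration: a 200-kb mini-chromosome carrying a
#' ~10-kb major-satellite-like tandem array (234-bp monomer, 5% divergence)
#' and 60 expressed genes; a ChIP library with 4-fold satellite weight and
#' expression-scaled TSS dips against a uniform input library; and MNase
#' ladders for bulk-like (187 bp) and satellite-like (200 bp) chromatin.
#' Every stage of [run_pipeline()] is driven by this one list, which can be
#' round-tripped through YAML.
#'
#' @param out_dir Output directory for all pipeline artifacts.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A named list understood by [run_pipeline()].
#' @export
demo_config <- function(out_dir, seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    genome = list(
      chrom = "chr1", length = 200000L, at_fraction = 0.58,
      satellite = list(name = "satMajor", class = "satMajor",
                       start = 150000L, monomer_length = 234L, copies = 43L,
                       divergence = 0.05),
      n_genes = 60L, gene_length = 2000L,
      gene_region_start = 5000L, gene_region_end = 140000L
    ),
    reads = list(read_len = 50L, fragment_len = 200L),
    chip = list(satellite_weight = 4, dip_depth = 0.9, dip_sigma = 250,
                n_reads = 30000L),
    input = list(n_reads = 30000L),
    signal = list(window = 100L),
    metagene = list(flank = 5000L, bin = 100L),
    correlate = list(window = 1000L),
    islands = list(window = 200L, gap = 600L, evalue = 1000,
                   effective_fraction = 0.8, q_threshold = 0.001,
                   p0 = 0.2, n_background = 5L),
    repeats = list(seed_len = 35L, max_mismatch = 2L, n_decoys = 2L),
    ladders = list(
      list(label = "bulk", nrl0 = 187, rate = 1,
           timepoints = c(2.5, 5, 10), n_bands = 8L, noise_sd = 5),
      list(label = "major_satellite", nrl0 = 200, rate = 1,
           timepoints = c(2.5, 5, 10), n_bands = 8L, noise_sd = 5)
    )
  )
}

#' Random AT-rich satellite-like monomer sequence
#'
#' Convenience generator for synthetic repeat monomers: an i.i.d. random
#' sequence at the given AT fraction (pericentromeric satellite DNA is
#' AT-rich), a pure function of the seed.
#'
#' @param len Monomer length in bp.
#' @param seed Integer seed.
#' @param at AT fraction.
#' @return A character scalar of A/C/G/T.
#' @export
satellite_monomer <- function(len, seed, at = 0.7) {
  with_seed(seed, paste(
    sample(c("A", "T", "C", "G"), len, replace = TRUE,
           prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
    collapse = ""
  ))
}

# Genome spec from the config's genome block: evenly spaced genes with
# log-normal expression, one satellite array.
config_genome_spec <- function(cfg) {
  g <- cfg$genome
  mono <- satellite_monomer(g$satellite$monomer_length, cfg$seed + 101L)
  repeats <- tibble(
    name = g$satellite$name, class = g$satellite$class, chrom = g$chrom,
    start = as.integer(g$satellite$start), monomer = mono,
    copies = as.integer(g$satellite$copies),
    divergence = g$satellite$divergence
  )
  n <- g$n_genes
  span <- g$gene_region_end - g$gene_region_start
  pitch <- span %/% n
  if (pitch <= g$gene_length) abort("gene region too small for n_genes")
  starts <- g$gene_region_start + pitch * (seq_len(n) - 1L)
  genes <- with_seed(cfg$seed + 202L, tibble(
    gene_id = sprintf("gene_%03d", seq_len(n)),
    chrom = g$chrom,
    start = as.integer(starts),
    end = as.integer(starts + g$gene_length),
    strand = sample(c("+", "-"), n, replace = TRUE),
    expression = round(stats::rlnorm(n, meanlog = 2, sdlog = 1.5), 3)
  ))
  genome_spec(setNames(g$length, g$chrom), repeats = repeats, genes = genes,
              at_fraction = g$at_fraction)
}

#' Run the analysis pipeline end to end
#'
#' Executes the stages in order: `simulate` (genome, ChIP/input libraries,
#' MNase ladders, repeat library) then `signal` (windowed coverage, per-10M
#' normalization, IP-IN, GC%), `metagene`, `correlate`, `islands`,
#' `repeats`, and `quant`. Every output is written under `config$out_dir` as
#' plain text (FASTA/FASTQ/BED/bedGraph/TSV) and listed in a manifest with
#' its MD5 hash; the config is echoed as YAML. Reruns with an identical
#' config are byte-identical. If `simulate` is not among the requested
#' stages, earlier outputs must already exist in `out_dir`.
#'
#' @param config A config list (see [demo_config()]) or the path of a YAML
#'   file holding one.
#' @param stages Character vector of stage names, or `"all"`.
#' @return The manifest tibble (`file`, `md5`), invisibly.
#' @export
run_pipeline <- function(config, stages = "all") {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(sprintf("config file does not exist: %s", config))
    }
    config <- yaml::read_yaml(config)
  }
  all_stages <- c("simulate", "signal", "metagene", "correlate", "islands",
                  "repeats", "quant")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  log_stage <- function(name) {
    message(sprintf("[satchrom] stage %s", name))
  }

  if ("simulate" %in% stages) {
    log_stage("simulate")
    spec <- config_genome_spec(config)
    built <- build_genome(spec, seed = config$seed + 1L)
    write_genome_fasta(built$genome, p("genome.fa"))
    write_bed6(dplyr::mutate(built$features, name = .data$name, score = 0),
               p("features.bed"))
    genes <- genes_from_features(built$features)
    readr::write_tsv(genes, p("genes.tsv"))
    enrich_chip <- enrichment_spec(
      class_weights = setNames(config$chip$satellite_weight,
                               config$genome$satellite$class),
      dip_depth = config$chip$dip_depth, dip_sigma = config$chip$dip_sigma
    )
    chip <- simulate_library(built$genome, built$features, enrich_chip,
                             n_reads = config$chip$n_reads,
                             read_len = config$reads$read_len,
                             fragment_len = config$reads$fragment_len,
                             seed = config$seed + 2L)
    input <- simulate_library(built$genome, built$features, enrichment_spec(),
                              n_reads = config$input$n_reads,
                              read_len = config$reads$read_len,
                              fragment_len = config$reads$fragment_len,
                              seed = config$seed + 3L)
    write_reads_fastq(chip, p("chip.fastq"))
    write_reads_fastq(input, p("input.fastq"))
    for (nm in c("chip", "input")) {
      lib <- if (nm == "chip") chip else input
      write_bed6(tibble(chrom = lib$chrom, start = lib$fragment_start,
                        end = lib$fragment_end, name = lib$read_id,
                        score = 0, strand = lib$strand),
                 p(paste0(nm, "_origins.bed")))
    }
    lib <- demo_repeat_library(spec, config)
    Biostrings::writeXStringSet(
      setNames(Biostrings::DNAStringSet(lib$consensus),
               paste0(lib$name, "|", lib$class)),
      p("repeat_library.fa")
    )
    for (i in seq_along(config$ladders)) {
      ld <- config$ladders[[i]]
      obs <- simulate_mnase_ladder(
        ladder_spec(nrl0 = ld$nrl0, rate = ld$rate,
                    timepoints = ld$timepoints, n_bands = ld$n_bands,
                    noise_sd = ld$noise_sd),
        seed = config$seed + 10L + i
      )
      readr::write_tsv(obs, p(paste0("ladder_", ld$label, ".tsv")))
    }
  }

  need <- function(f) {
    path <- p(f)
    if (!file.exists(path)) {
      abort(sprintf("required pipeline input does not exist: %s", path))
    }
    path
  }
  genome <- Biostrings::readDNAStringSet(need("genome.fa"))
  chrom_sizes <- setNames(Biostrings::width(genome), names(genome))
  genes <- read_genes_tsv(need("genes.tsv"))
  chip_bed <- read_bed6(need("chip_origins.bed"))
  input_bed <- read_bed6(need("input_origins.bed"))
  w <- config$signal$window

  chip_raw <- window_counts(chip_bed, chrom_sizes, w = w)
  input_raw <- window_counts(input_bed, chrom_sizes, w = w)
  chip_norm <- normalize_per_10m(chip_raw)
  input_norm <- normalize_per_10m(input_raw)
  diff_track <- ipin(chip_norm, input_norm)
  gc <- gc_track(genome, w = w)

  if ("signal" %in% stages) {
    log_stage("signal")
    write_bedgraph(chip_norm, p("chip_per10M.bedgraph"))
    write_bedgraph(input_norm, p("input_per10M.bedgraph"))
    write_bedgraph(diff_track, p("ipin.bedgraph"))
    write_bedgraph(gc, p("gc.bedgraph"))
  }

  if ("metagene" %in% stages) {
    log_stage("metagene")
    grouping <- partition_by_expression(genes, "deciles_extremes")
    prof <- metagene_profile(diff_track, genes, grouping, anchor = "tss",
                             flank = config$metagene$flank,
                             bin = config$metagene$bin)
    readr::write_tsv(prof, p("metagene_tss.tsv"))
  }

  if ("correlate" %in% stages) {
    log_stage("correlate")
    cors <- dplyr::bind_rows(
      genome_correlation(chip_norm, input_norm, W = config$correlate$window,
                         label_a = "chip", label_b = "input"),
      genome_correlation(diff_track, gc, W = config$correlate$window,
                         label_a = "ipin", label_b = "gc"),
      per_chromosome_correlation(chip_norm, input_norm,
                                 W = config$correlate$window,
                                 label_a = "chip", label_b = "input")
    )
    readr::write_tsv(cors, p("correlations.tsv"))
  }

  if ("islands" %in% stages) {
    log_stage("islands")
    iw <- config$islands$window
    ip <- island_params(window = iw, gap = config$islands$gap,
                        evalue = config$islands$evalue,
                        effective_fraction = config$islands$effective_fraction,
                        q_threshold = config$islands$q_threshold,
                        p0 = config$islands$p0,
                        n_background = config$islands$n_background)
    chip_w <- window_counts(chip_bed, chrom_sizes, w = iw)
    input_w <- window_counts(input_bed, chrom_sizes, w = iw)
    isl <- call_islands(chip_w, input_w, ip, seed = config$seed + 20L)
    write_bed6(tibble(chrom = isl$chrom, start = isl$start, end = isl$end,
                      name = sprintf("island_%d", seq_len(nrow(isl))),
                      score = round(isl$score * 10), strand = "."),
               p("islands.bed"))
    opt <- optimize_gap(chip_w, input_w, ip, seed = config$seed + 20L)
    readr::write_tsv(
      dplyr::mutate(opt$diagnostics, best = .data$gap == opt$best_gap),
      p("gap_optimization.tsv")
    )
    ann <- annotate_regions(isl, genes)
    readr::write_tsv(ann$breakdown, p("island_annotation.tsv"))
  }

  if ("repeats" %in% stages) {
    log_stage("repeats")
    lib <- read_repeat_library(need("repeat_library.fa"))
    chip_reads <- read_reads_fastq(need("chip.fastq"))
    input_reads <- read_reads_fastq(need("input.fastq"))
    chip_asn <- assign_reads_to_repeats(chip_reads, lib,
                                        seed_len = config$repeats$seed_len,
                                        max_mismatch = config$repeats$max_mismatch,
                                        rng_seed = config$seed + 30L)
    input_asn <- assign_reads_to_repeats(input_reads, lib,
                                         seed_len = config$repeats$seed_len,
                                         max_mismatch = config$repeats$max_mismatch,
                                         rng_seed = config$seed + 31L)
    readr::write_tsv(chip_asn, p("chip_read_assignment.tsv"))
    tab <- repeat_enrichment_table(chip_asn, input_asn,
                                   chip_total = nrow(chip_reads),
                                   input_total = nrow(input_reads),
                                   library = lib)
    readr::write_tsv(tab, p("repeat_enrichment.tsv"))
  }

  if ("quant" %in% stages) {
    log_stage("quant")
    nrl <- purrr::map_dfr(config$ladders, function(ld) {
      obs <- readr::read_tsv(need(paste0("ladder_", ld$label, ".tsv")),
                             col_types = "did", progress = FALSE)
      fit <- nrl_extrapolate(obs)
      tibble(label = ld$label, nrl0_bp = fit$nrl0, se_bp = fit$se,
             rate_bp_per_min = fit$rate)
    })
    readr::write_tsv(nrl, p("nrl_estimates.tsv"))
  }

  yaml::write_yaml(config, p("config.yaml"))
  files <- sort(setdiff(list.files(config$out_dir), "manifest.tsv"))
  manifest <- tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$out_dir, files)))
  )
  readr::write_tsv(manifest, p("manifest.tsv"))
  invisible(manifest)
}

# Repeat library for the demo: the satellite consensus plus seeded decoy
# entries that match nothing in the genome.
demo_repeat_library <- function(spec, config) {
  decoys <- with_seed(config$seed + 303L, {
    purrr::map_chr(seq_len(config$repeats$n_decoys), function(i) {
      paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    })
  })
  repeat_library(tibble(
    name = c(spec$repeats$name, sprintf("decoy_%d", seq_along(decoys))),
    class = c(spec$repeats$class, sprintf("decoy_%d", seq_along(decoys))),
    consensus = c(spec$repeats$monomer, decoys)
  ))
}
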