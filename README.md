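# satchrom

Linker histone (H1) ChIP-seq occupancy and satellite chromatin analysis in R.

Linker histones bind the nucleosome at the DNA entry/exit site and the linker
between nucleosomes, promoting chromatin folding. Mapping where H1 variants
sit genome-wide is harder than for core-histone marks: H1 is depleted at
active promoters, enriched in AT-rich heterochromatin, and its strongest
binding sites — pericentromeric major satellite arrays — are tandem repeats
where reads multi-map and per-locus coverage is meaningless. `satchrom`
implements the computational toolkit for this setting, for epigenomics
analysts working with ChIP-seq of H1 variants (or any occupancy-style
factor) and with MNase digestion assays of repeat chromatin:

* **Windowed coverage and IP−IN tracks** — read counts per `w`-bp tiling
  window, normalized to 10 million mapped reads, with the input control
  subtracted: `IP−IN = 10⁷·c_IP/N_IP − 10⁷·c_IN/N_IN` per window. GC% tracks
  computed from sequence on the same grid.
* **Repeat-class enrichment with multiread handling** — the first 35 bp of
  each read is matched against a repeat consensus library (each consensus
  doubled so seeds crossing tandem-monomer junctions are found, both
  strands, ≤ 2 mismatches, `N` never matches); reads hitting several entries
  are placed uniformly at random among them. Per class: percent of library
  reads mapped, fold enrichment `%ChIP / %input`, and a two-sided Fisher
  exact p-value on the 2×2 in/out-of-class table.
* **Metagene profiles** — mean IP−IN in 100-bp gene-relative bins around the
  TSS or TTS, strand-flipped to read 5′→3′, for gene groups defined by
  expression quantiles, promoter histone-mark level, or H3K4me3/H3K27me3
  bivalency; plus signal-vs-distance decay with exclusion of points near
  neighbouring TSSs.
* **Genome-wide correlation** — Pearson R between tracks summed to 1-kb
  windows, pooled across chromosomes or per chromosome.
* **SICER-style island calling** — 200-bp windows eligible when their count's
  upper-tail Poisson p (at background rate λ = N·w / (0.8·genome)) is ≤ 0.2;
  eligible windows merged across ≤ 600 bp gaps; island score = Σ −ln p;
  score threshold from a seeded Monte Carlo uniform background at E = 1000;
  FDR vs islands called on the input (BH, q ≤ 0.001). Gap-size optimization
  over {0, 200, 400, 600}, common/unique region sets, top-10% selection,
  and genic/proximal/distal annotation.
* **Closed-form estimators** — nucleosome repeat length (NRL) as the OLS
  slope of polynucleosome band size on band number per MNase timepoint,
  extrapolated to digestion time zero; H1 per nucleosome from
  peptide-bond-adjusted A₂₁₄ peak areas (`Σ H1ᵢ/bondsᵢ ÷ (H2B/bonds)/2`);
  qRT-PCR relative expression `(RT⁺−RT⁻)target / (RT⁺−RT⁻)reference`; qChIP
  enrichment over IgG; percent methylated CpG.
* **A synthetic-data generator** — mini-genomes with divergent tandem
  satellite arrays and expressed genes, ChIP/input libraries with known
  class weights and expression-scaled Gaussian TSS dips, and MNase ladders
  `S(n,t) = n·(NRL₀ − r·t) + b + ε` — so the whole pipeline is testable with
  no external data.

Everything is tidyverse-shaped: tibbles in and out, pipe-friendly,
`autoplot()` for the main result types, `tidy()`/`glance()` for fitted
objects.

## Worked example

Simulate a 500-kb genome carrying a 25-kb major-satellite-like array (5% of
the genome, 250-bp monomer, 5% per-base divergence), draw a ChIP library
with 4-fold satellite weight against a uniform input, and quantify repeat
enrichment end to end:

```r
library(satchrom)

mono <- satellite_monomer(250, seed = 11)
sp <- genome_spec(
  c(chr1 = 500000),
  repeats = tibble::tibble(name = "satMajor", class = "satMajor",
                           chrom = "chr1", start = 200000, monomer = mono,
                           copies = 100, divergence = 0.05)
)
built <- build_genome(sp, seed = 12)
lib <- repeat_library(tibble::tibble(
  name = c("satMajor", "decoy"), class = c("satMajor", "decoy"),
  consensus = c(mono, satellite_monomer(300, seed = 13))
))
chip  <- simulate_library(built$genome, built$features,
                          enrichment_spec(class_weights = c(satMajor = 4)),
                          n_reads = 50000, seed = 14)
input <- simulate_library(built$genome, built$features, enrichment_spec(),
                          n_reads = 50000, seed = 15)
repeat_enrichment_table(
  assign_reads_to_repeats(chip, lib, rng_seed = 16),
  assign_reads_to_repeats(input, lib, rng_seed = 17),
  chip_total = 50000, input_total = 50000, library = lib
) |> dplyr::select(class, chip_pct, input_pct, fold, p_value)
#> # A tibble: 2 × 5
#>   class    chip_pct input_pct   fold p_value
#>   <chr>       <dbl>     <dbl>  <dbl>   <dbl>
#> 1 decoy         0        0    NaN          1
#> 2 satMajor     12.2      3.64   3.34       0
```

12.2% of ChIP reads versus 3.6% of input reads carry a satellite seed: the
class is 3.3-fold enriched (the sampling model predicts
`f/(1+s(f−1)) = 3.48` for weight `f = 4` at genomic fraction `s = 0.05`;
about a quarter of array reads exceed the 2-mismatch seed budget at 5%
divergence, which cancels between numerator and denominator). The decoy
class catches nothing, and the Fisher p-value is numerically zero.

Estimate the nucleosome repeat length from a simulated MNase time course of
satellite-like chromatin (true NRL₀ = 200 bp, 1 bp/min apparent shortening,
5-bp band noise):

```r
obs <- simulate_mnase_ladder(ladder_spec(nrl0 = 200, rate = 1, noise_sd = 5),
                             seed = 18)
fit <- nrl_extrapolate(obs)
fit
#> NRL at time 0: 200.1 bp (SE 0.00); shortening 1.01 bp/min
glance(fit)
#> # A tibble: 1 × 5
#>   nrl0_bp    se_bp rate_bp_per_min n_timepoints r.squared
#>     <dbl>    <dbl>           <dbl>        <int>     <dbl>
#> 1    200. 0.000916            1.01            3     1.000
```

The slope of band size on band number at each digestion time is the
apparent NRL; regressing those slopes on time and reading the intercept
recovers the zero-time NRL within a fraction of a base pair here.

The bundled demo pipeline runs every stage (simulate → coverage/IP−IN →
metagene → correlation → islands → repeats → NRL) from one config and
writes plain-text artifacts plus an MD5 manifest:

```r
run_pipeline(demo_config("demo_out", seed = 1))
```

or from a shell: `Rscript inst/scripts/satchrom-pipeline.R --demo demo_out`.

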