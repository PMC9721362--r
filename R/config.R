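#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults emulate
#' the statistical structure of an EMS-mutagenized soybean line profiled with
#' resequencing, two single-library RNA-seq runs and MethylC-seq:
#' predominantly heterozygous SNPs (94.6%), a transition-biased spectrum
#' giving Ti/Tv close to 1.43 (transition fraction 0.589), small indels
#' (< 50 bp), negative-binomial counts with planted two-fold DE genes, and a
#' methylome with roughly 57.6% / 32.8% / 2.6% of CG / CHG / CHH cytosines
#' methylated and a bisulfite non-conversion rate of 4e-4 (conversion 99.96%).
#'
#' @param seed master integer seed; every generator stage derives its own
#'   substream from it, so adding stages never perturbs earlier outputs.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_genes total number of genes laid out across chromosomes.
#' @param snp_rate per-bp probability of a SNP.
#' @param transition_fraction probability that a SNP is a transition
#'   (A<->G, C<->T). The default 0.589 gives Ti/Tv = 0.589/0.411 = 1.43.
#' @param het_fraction probability that a variant is heterozygous (0/1).
#' @param indel_rate per-bp probability of a small indel.
#' @param max_indel largest indel size in bp; must be < 50.
#' @param n_de_genes number of genes planted as differentially expressed
#'   (default: 10% of `n_genes`, the planted-DE proportion used throughout
#'   the package's recovery checks).
#' @param de_log2fc absolute planted log2 fold change (mutant over control).
#' @param nb_dispersion negative-binomial dispersion of the count model.
#'   The default 0.01 is technical-replicate-scale overdispersion, matching
#'   the single-library-per-condition design the DE test assumes.
#' @param mean_count mean expression count per gene and library.
#' @param lib_size_ratio mutant/control library-depth ratio (default 1).
#' @param meth_level_cg,meth_level_chg,meth_level_chh per-context probability
#'   that a cytosine is methylated.
#' @param methylated_ml true methylation level of a methylated cytosine.
#' @param n_dmrs number of planted differentially methylated regions.
#' @param dmr_delta methylation-level shift inside planted DMRs (mutant
#'   minus control; sign alternates hyper/hypo across DMRs).
#' @param dmr_length planted DMR length in bp.
#' @param read_depth mean bisulfite read depth per cytosine (Poisson).
#' @param nonconversion_rate bisulfite non-conversion rate r: probability an
#'   unmethylated cytosine spuriously reads as methylated.
#' @param control_seq_length length of the unmethylated spike-in control
#'   sequence (FASTA record `control_unmethylated`).
#' @param gene_flank minimum bp between adjacent genes and chromosome ends,
#'   so upstream/downstream/intergenic classes all occur (default 12 kb).
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 5, chrom_length = 1e5)
#' cfg$transition_fraction
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 200000L,
                       n_genes = 20L,
                       snp_rate = 5e-4,
                       transition_fraction = 0.589,
                       het_fraction = 0.946,
                       indel_rate = 5e-5,
                       max_indel = 49L,
                       n_de_genes = NULL,
                       de_log2fc = 2,
                       nb_dispersion = 0.01,
                       mean_count = 50,
                       lib_size_ratio = 1,
                       meth_level_cg = 0.576,
                       meth_level_chg = 0.328,
                       meth_level_chh = 0.026,
                       methylated_ml = 0.8,
                       n_dmrs = 4L,
                       dmr_delta = 0.4,
                       dmr_length = 4000L,
                       read_depth = 20,
                       nonconversion_rate = 4e-4,
                       control_seq_length = 20000L,
                       gene_flank = 12000L) {
  if (is.null(n_de_genes)) n_de_genes <- round(0.1 * n_genes)
  cfg <- list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
    snp_rate = snp_rate, transition_fraction = transition_fraction,
    het_fraction = het_fraction, indel_rate = indel_rate,
    max_indel = as.integer(max_indel), n_de_genes = as.integer(n_de_genes),
    de_log2fc = de_log2fc, nb_dispersion = nb_dispersion,
    mean_count = mean_count, lib_size_ratio = lib_size_ratio,
    meth_level_cg = meth_level_cg, meth_level_chg = meth_level_chg,
    meth_level_chh = meth_level_chh, methylated_ml = methylated_ml,
    n_dmrs = as.integer(n_dmrs), dmr_delta = dmr_delta,
    dmr_length = as.integer(dmr_length), read_depth = read_depth,
    nonconversion_rate = nonconversion_rate,
    control_seq_length = as.integer(control_seq_length),
    gene_flank = as.integer(gene_flank)
  )
  probs <- c("snp_rate", "transition_fraction", "het_fraction", "indel_rate",
             "meth_level_cg", "meth_level_chg", "meth_level_chh",
             "methylated_ml", "nonconversion_rate")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("sim_config: '", p, "' must be a probability in [0, 1]")
  }
  if (cfg$max_indel >= 50L || cfg$max_indel < 1L)
    stop("sim_config: 'max_indel' must be in [1, 49] (indels are < 50 bp)")
  if (cfg$dmr_delta <= 0 || cfg$dmr_delta > 1)
    stop("sim_config: 'dmr_delta' must be in (0, 1]")
  if (cfg$nb_dispersion < 0) stop("sim_config: 'nb_dispersion' must be >= 0")
  if (cfg$mean_count <= 0) stop("sim_config: 'mean_count' must be > 0")
  if (cfg$read_depth <= 0) stop("sim_config: 'read_depth' must be > 0")
  if (cfg$lib_size_ratio <= 0) stop("sim_config: 'lib_size_ratio' must be > 0")
  if (cfg$n_genes < 0L || cfg$n_chromosomes < 1L || cfg$chrom_length < 1000L)
    stop("sim_config: invalid genome dimensions")
  if (cfg$n_de_genes > cfg$n_genes)
    stop("sim_config: 'n_de_genes' cannot exceed 'n_genes'")
  structure(cfg, class = "sim_config")
}

#' Pipeline analysis parameters
#'
#' Analysis-stage thresholds with their conventional defaults: DE calling at
#' BH-adjusted p < 0.005 and fold change >= 2; methylation windows of
#' 3,000 bp sliding by 600 bp; gene flanks of 5,000 bp for variant region
#' classes; 2,000 bp promoters for CpG-island extraction and DMR-to-gene
#' assignment; site calling at 5x minimum coverage and FDR 0.05.
#'
#' @param deg_padj adjusted-p threshold for DE calls.
#' @param deg_lfc minimum absolute log2 fold change for DE calls.
#' @param pseudocount pseudocount applied when a fold-change operand is zero.
#' @param window_size,step_size methylation sliding-window geometry in bp.
#' @param site_min_coverage minimum read coverage for site calling.
#' @param site_fdr FDR for binomial methylation-site calls.
#' @param dmr_fdr FDR for per-window differential tests.
#' @param dmr_min_delta minimum absolute methylation-level difference of a DMR.
#' @param dmr_min_sites minimum covered cytosines inside a DMR.
#' @param variant_flank gene-flank width (bp) for upstream/downstream classes.
#' @param splice_site_on `"intron"` (conventional: first/last 2 bp of an
#'   intron) or `"exon"` (first/last 2 bp of an exon).
#' @param promoter_bp promoter width (bp) for CGI extraction and DMR overlap.
#' @param cgi_window,cgi_shift,cgi_min_gc,cgi_min_oe,cgi_min_length CpG-island
#'   scan parameters (Gardiner-Garden & Frommer defaults).
#' @param integration_classes variant-effect classes defining the mutated
#'   gene set; `"large_impact"` or `"nonsynonymous_only"`.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(deg_padj = 0.005,
                            deg_lfc = 1,
                            pseudocount = 0.1,
                            window_size = 3000L,
                            step_size = 600L,
                            site_min_coverage = 5L,
                            site_fdr = 0.05,
                            dmr_fdr = 0.05,
                            dmr_min_delta = 0.1,
                            dmr_min_sites = 3L,
                            variant_flank = 5000L,
                            splice_site_on = c("intron", "exon"),
                            promoter_bp = 2000L,
                            cgi_window = 100L,
                            cgi_shift = 1L,
                            cgi_min_gc = 50,
                            cgi_min_oe = 0.6,
                            cgi_min_length = 200L,
                            integration_classes = c("large_impact",
                                                    "nonsynonymous_only")) {
  splice_site_on <- match.arg(splice_site_on)
  integration_classes <- match.arg(integration_classes)
  structure(list(
    deg_padj = deg_padj, deg_lfc = deg_lfc, pseudocount = pseudocount,
    window_size = as.integer(window_size), step_size = as.integer(step_size),
    site_min_coverage = as.integer(site_min_coverage), site_fdr = site_fdr,
    dmr_fdr = dmr_fdr, dmr_min_delta = dmr_min_delta,
    dmr_min_sites = as.integer(dmr_min_sites),
    variant_flank = as.integer(variant_flank),
    splice_site_on = splice_site_on, promoter_bp = as.integer(promoter_bp),
    cgi_window = as.integer(cgi_window), cgi_shift = as.integer(cgi_shift),
    cgi_min_gc = cgi_min_gc, cgi_min_oe = cgi_min_oe,
    cgi_min_length = as.integer(cgi_min_length),
    integration_classes = integration_classes
  ), class = "pipeline_config")
}

#' Derive a stage-specific seed from the master seed
#'
#' Each generator stage gets an independent, reproducible substream keyed by
#' the stage name, so adding or reordering stages never changes the output
#' of the others.
#'
#' @param seed master integer seed.
#' @param stage stage name, e.g. `"variants"`.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}
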