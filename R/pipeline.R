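#' Run the full multi-omics pipeline on simulated data
#'
#' Chains every stage end-to-end: simulate genome, variants, counts and
#' methylome; write all interchange files (FASTA, GFF3, VCF, count TSV,
#' cytosine reports, truth JSON); read them back through the package's own
#' readers; annotate variants; run the no-replicate DE analysis; estimate
#' non-conversion, call sites, build windows and call DMRs; predict CpG
#' islands over DEGs and classify methylation-expression patterns; and
#' integrate the three gene sets. Outputs (effect TSV, DEG TSV, DMR
#' BED/TSV, CGI table, integration JSON, run log) are written under
#' `outdir`.
#'
#' @param config a [sim_config()].
#' @param params a [pipeline_config()].
#' @param outdir output directory (created if missing).
#' @param planted_genes optional gene ids planted as simultaneously DE,
#'   nonsynonymously mutated and DMR-overlapping.
#' @return A list with every intermediate and final object: `sim`,
#'   `variants`, `effects`, `deg`, `nonconversion`, `site_calls`,
#'   `windows`, `dmrs`, `islands`, `patterns`, `integration`,
#'   `candidates`, `truth`.
#' @export
run_pipeline <- function(config = sim_config(),
                         params = pipeline_config(),
                         outdir = tempfile("emsomics_run_"),
                         planted_genes = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = config$seed, params = unclass(params))

  # --- simulate and write -------------------------------------------------
  sim <- simulate_genome(config)
  if (!is.null(planted_genes)) {
    de_truth_forced <- planted_genes
  } else de_truth_forced <- NULL
  vs <- simulate_variants(sim, config, planted_genes = planted_genes)
  cts <- simulate_counts(sim$annotation, config)
  if (!is.null(de_truth_forced)) {
    # force planted genes to be DE as well (shift the mutant count)
    for (gid in de_truth_forced) {
      i <- match(gid, cts$counts$gene_id)
      cts$counts$count_mutant[i] <-
        as.integer(round((cts$counts$count_control[i] + 25) *
                           2^config$de_log2fc))
      if (!gid %in% cts$truth$gene_id)
        cts$truth <- rbind(cts$truth, data.frame(gene_id = gid,
                                                 direction = "up"))
    }
  }
  meth <- simulate_methylome(sim, config, dmr_in_genes = planted_genes)

  paths <- list(
    fasta = file.path(outdir, "genome.fasta"),
    gff3 = file.path(outdir, "genes.gff3"),
    vcf = file.path(outdir, "variants.vcf"),
    counts = file.path(outdir, "counts.tsv"),
    cx_control = file.path(outdir, "cytosines_control.tsv"),
    cx_mutant = file.path(outdir, "cytosines_mutant.tsv"),
    truth = file.path(outdir, "truth.json"))
  write_fasta(sim$genome, paths$fasta)
  write_gff3(sim$annotation, paths$gff3)
  chrom_lengths <- vapply(sim$genome, nchar, integer(1))
  write_vcf(vs$variants, chrom_lengths, paths$vcf)
  write_counts(cts$counts, paths$counts)
  write_cytosine_report(meth$sites_control, paths$cx_control)
  write_cytosine_report(meth$sites_mutant, paths$cx_mutant)
  truth <- list(variant_effects = vs$truth, de_genes = cts$truth,
                dmrs = meth$truth)
  jsonlite::write_json(truth, paths$truth, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)

  # --- read back and analyse ---------------------------------------------
  genome <- read_fasta(paths$fasta)
  annotation <- read_gff3(paths$gff3)
  variants <- read_vcf(paths$vcf, genome = genome)
  counts <- read_counts(paths$counts)
  sites_control <- read_cytosine_report(paths$cx_control)
  sites_mutant <- read_cytosine_report(paths$cx_mutant)

  effects <- annotate_variants(variants, genome, annotation,
                               flank = params$variant_flank,
                               splice_site_on = params$splice_site_on)
  write.table(effects, file.path(outdir, "effects.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summaries <- variant_summaries(variants, effects)

  deg <- run_deg(counts, padj_threshold = params$deg_padj,
                 lfc_threshold = params$deg_lfc,
                 pseudocount = params$pseudocount)
  write.table(deg, file.path(outdir, "deg.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  ctrl_idx <- sites_control$chrom == "control_unmethylated"
  nc_control <- estimate_nonconversion(sites_control[ctrl_idx, ])
  nc_mutant <- estimate_nonconversion(
    sites_mutant[sites_mutant$chrom == "control_unmethylated", ])
  genomic_c <- sites_control[!ctrl_idx, ]
  genomic_m <- sites_mutant[sites_mutant$chrom != "control_unmethylated", ]
  calls_c <- call_sites(genomic_c, nc_control$rate,
                        min_coverage = params$site_min_coverage,
                        fdr = params$site_fdr)
  calls_m <- call_sites(genomic_m, nc_mutant$rate,
                        min_coverage = params$site_min_coverage,
                        fdr = params$site_fdr)
  chrom_lens <- chrom_lengths[setdiff(names(chrom_lengths),
                                      "control_unmethylated")]
  win_c <- make_windows(genomic_c, chrom_lens, params$window_size,
                        params$step_size)
  win_m <- make_windows(genomic_m, chrom_lens, params$window_size,
                        params$step_size)
  dmrs <- call_dmrs(win_c, win_m, genomic_c, genomic_m,
                    fdr = params$dmr_fdr,
                    min_delta = params$dmr_min_delta,
                    min_sites = params$dmr_min_sites)
  if (nrow(dmrs))
    write_bed(dmrs, file.path(outdir, "dmrs.bed"), name_col = "direction")
  write.table(dmrs, file.path(outdir, "dmrs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  deg_ids <- deg$gene_id[deg$status != "ns"]
  islands <- find_gene_cgis(annotation, genome, gene_ids = deg_ids,
                            promoter_bp = params$promoter_bp,
                            window = params$cgi_window,
                            shift = params$cgi_shift,
                            min_gc = params$cgi_min_gc,
                            min_oe = params$cgi_min_oe,
                            min_length = params$cgi_min_length)
  calls_list <- list(control = calls_c, mutant = calls_m)
  patterns <- cgi_pattern_table(deg, islands, calls_list)
  write.table(islands, file.path(outdir, "cgi.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  classes <- if (params$integration_classes == "nonsynonymous_only")
    "nonsynonymous" else LARGE_IMPACT_CLASSES
  set_R <- mutated_gene_set(effects, classes = classes)
  set_M <- assign_dmr_genes(dmrs, annotation,
                            promoter_bp = params$promoter_bp)
  integration <- overlap_sets(set_R, deg_ids, set_M)
  candidates <- candidate_report(integration, deg)
  jsonlite::write_json(
    list(counts = as.list(integration$counts),
         intersections = integration$intersections,
         pct_T_with_R = integration$pct_T_with_R),
    file.path(outdir, "integration.json"), auto_unbox = TRUE, digits = NA)
  write.table(candidates, file.path(outdir, "candidates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  log$record_counts <- list(
    variants = nrow(variants), effects = nrow(effects),
    genes_tested = nrow(deg), degs = length(deg_ids),
    sites = nrow(genomic_c), windows = nrow(win_c), dmrs = nrow(dmrs),
    islands = nrow(islands))
  log$nonconversion <- list(control = nc_control$rate,
                            mutant = nc_mutant$rate)
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)

  list(sim = sim, variants = variants, effects = effects,
       summaries = summaries, deg = deg,
       nonconversion = list(control = nc_control, mutant = nc_mutant),
       site_calls = calls_list,
       windows = list(control = win_c, mutant = win_m), dmrs = dmrs,
       islands = islands, patterns = patterns, integration = integration,
       candidates = candidates, truth = truth, outdir = outdir)
}
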