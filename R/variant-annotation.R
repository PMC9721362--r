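#' Classify the genomic region of variants
#'
#' Assigns each variant a single region label against the gene models, with
#' priority CDS (`exon`) over splice site over UTR over intron over gene
#' flank over intergenic. Flanks extend `flank` bp from the gene span,
#' strand-aware (`upstream_5kb` / `downstream_5kb` at the default width);
#' a flank variant is assigned to the nearest gene, exact ties to the
#' lexicographically smaller gene id. Indels are classified by their first
#' affected base (VCF left-anchored convention).
#'
#' @param variants data frame with `chrom`, `pos`, `ref`, `alt`.
#' @param annotation a `gene_annotation` list.
#' @param chroms optional character vector of valid chromosome names; a
#'   variant on a chromosome outside it raises an unplaced-variant error.
#' @param flank flank width in bp (default 5000).
#' @param splice_site_on `"intron"` (default) or `"exon"` splice-site
#'   convention.
#' @return The input data frame with `gene_id` and `region` columns added;
#'   one row per variant-gene pair (a variant inside two overlapping genes
#'   yields two rows).
#' @export
classify_region <- function(variants, annotation, chroms = NULL,
                            flank = 5000L,
                            splice_site_on = c("intron", "exon")) {
  splice_site_on <- match.arg(splice_site_on)
  if (!is.null(chroms)) {
    bad <- setdiff(unique(variants$chrom), chroms)
    if (length(bad))
      stop("unplaced variant(s): chromosome(s) ",
           paste(bad, collapse = ", "), " absent from the annotation")
  }
  genes <- annotation$genes
  n <- nrow(variants)
  vtype <- mapply(variant_type, variants$ref, variants$alt, USE.NAMES = FALSE)
  anchor <- ifelse(vtype == "deletion", variants$pos + 1L, variants$pos)
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(anchor, width = 1L))

  idx <- region_index(annotation, splice_site_on)
  assigned <- rep(FALSE, n)
  out <- vector("list", n)
  take <- function(class_gr, label) {
    if (!length(class_gr)) return(invisible())
    hits <- GenomicRanges::findOverlaps(vr, class_gr)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    keep <- !assigned[qh]
    for (k in which(keep)) {
      i <- qh[k]
      row <- cbind(variants[i, , drop = FALSE],
                   gene_id = class_gr$gene_id[sh[k]], region = label,
                   stringsAsFactors = FALSE)
      out[[i]] <<- rbind(out[[i]], row)
    }
    assigned[unique(qh)] <<- TRUE
  }
  if (splice_site_on == "exon") take(idx$splice, "splice_site")
  take(idx$cds, "exon")
  if (splice_site_on == "intron") take(idx$splice, "splice_site")
  take(idx$utr5, "utr5")
  take(idx$utr3, "utr3")
  take(idx$intron, "intron")

  # flanks for still-unassigned variants
  left <- which(!assigned)
  if (length(left) && nrow(genes)) {
    span <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$start, genes$end))
    ext <- GenomicRanges::resize(span, GenomicRanges::width(span) +
                                   2L * flank, fix = "center")
    hits <- GenomicRanges::findOverlaps(vr[left], ext)
    for (i in left) {
      js <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) ==
                                           match(i, left)]
      js <- js[genes$chrom[js] == variants$chrom[i]]
      if (length(js)) {
        d <- ifelse(anchor[i] < genes$start[js], genes$start[js] - anchor[i],
                    anchor[i] - genes$end[js])
        ok <- js[d >= 1L & d <= flank]
        if (length(ok)) {
          dd <- d[d >= 1L & d <= flank]
          j <- ok[order(dd, genes$gene_id[ok])][1L]
          upstream_side <- anchor[i] < genes$start[j]
          region <- if ((genes$strand[j] == "+") == upstream_side)
            "upstream_5kb" else "downstream_5kb"
          out[[i]] <- cbind(variants[i, , drop = FALSE],
                            gene_id = genes$gene_id[j], region = region,
                            stringsAsFactors = FALSE)
          assigned[i] <- TRUE
        }
      }
    }
  }
  for (i in which(!assigned))
    out[[i]] <- cbind(variants[i, , drop = FALSE],
                      gene_id = NA_character_, region = "intergenic",
                      stringsAsFactors = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Precomputed GRanges per region class, each carrying gene_id metadata.
region_index <- function(annotation, splice_site_on = "intron") {
  genes <- annotation$genes
  feats <- annotation$features
  gr_of <- function(df) {
    if (!nrow(df))
      return(GenomicRanges::GRanges())
    chrom <- genes$chrom[match(df$gene_id, genes$gene_id)]
    g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(df$start, df$end))
    g$gene_id <- df$gene_id
    g
  }
  pick <- function(type) feats[feats$type == type,
                               c("gene_id", "start", "end"), drop = FALSE]
  introns <- do.call(rbind, lapply(genes$gene_id, function(gid) {
    intr <- gene_introns(annotation, gid)
    if (!nrow(intr)) return(NULL)
    cbind(gene_id = gid, intr, stringsAsFactors = FALSE)
  }))
  if (is.null(introns))
    introns <- data.frame(gene_id = character(0), start = integer(0),
                          end = integer(0))
  splice <- do.call(rbind, lapply(genes$gene_id, function(gid) {
    st <- genes$strand[genes$gene_id == gid]
    sw <- splice_windows(annotation, gid, st, splice_site_on)
    both <- rbind(sw$donor, sw$acceptor)
    if (!nrow(both)) return(NULL)
    cbind(gene_id = gid, both, stringsAsFactors = FALSE)
  }))
  if (is.null(splice))
    splice <- data.frame(gene_id = character(0), start = integer(0),
                         end = integer(0))
  list(cds = gr_of(pick("CDS")), utr5 = gr_of(pick("five_prime_UTR")),
       utr3 = gr_of(pick("three_prime_UTR")), intron = gr_of(introns),
       splice = gr_of(splice))
}

#' Codon-level coding consequence of a variant within a gene
#'
#' For CDS SNPs the affected codon is located, mutated and translated:
#' synonymous, nonsynonymous, `stop_gained`, `stop_lost` or `start_lost`
#' (first codon no longer ATG). CDS indels become `frameshift` when their
#' size is not a multiple of three, else `codon_insertion`/`codon_deletion`.
#' Splice-site variants are labelled `splice_donor`/`splice_acceptor`, and a
#' 5' UTR SNP that creates a new ATG on the sense strand `start_gained`.
#' Amino-acid changes are formatted three-letter, e.g. `"Ser107Gly"`.
#'
#' @param variant one-row data frame (`chrom`, `pos`, `ref`, `alt`).
#' @param gene_id gene to evaluate against.
#' @param genome named character vector of sequences.
#' @param annotation a `gene_annotation` list.
#' @param region region label from [classify_region()]; computed when `NULL`.
#' @param splice_site_on splice-site convention, as in [classify_region()].
#' @return A list with `coding_effect` and `aa_change`.
#' @export
coding_effect <- function(variant, gene_id, genome, annotation,
                          region = NULL,
                          splice_site_on = c("intron", "exon")) {
  splice_site_on <- match.arg(splice_site_on)
  v <- variant
  if (is.null(region)) {
    cr <- classify_region(v, annotation, flank = 0L,
                          splice_site_on = splice_site_on)
    cr <- cr[!is.na(cr$gene_id) & cr$gene_id == gene_id, , drop = FALSE]
    if (!nrow(cr)) return(list(coding_effect = "none", aa_change = ""))
    region <- cr$region[1L]
  }
  vtype <- variant_type(v$ref, v$alt)
  g <- annotation$genes[annotation$genes$gene_id == gene_id, ]
  if (region == "splice_site") {
    anchor <- if (vtype == "deletion") v$pos + 1L else v$pos
    sw <- splice_windows(annotation, gene_id, g$strand, splice_site_on)
    eff <- if (in_any(anchor, sw$donor)) "splice_donor" else "splice_acceptor"
    return(list(coding_effect = eff, aa_change = ""))
  }
  if (region == "exon") {
    if (vtype != "snp") {
      size <- abs(nchar(v$alt) - nchar(v$ref))
      eff <- if (size %% 3L != 0L) "frameshift"
      else if (vtype == "insertion") "codon_insertion" else "codon_deletion"
      return(list(coding_effect = eff, aa_change = ""))
    }
    return(codon_snp_effect(v, gene_id, genome, annotation))
  }
  if (region == "utr5" && vtype == "snp") {
    ctx <- utr5_sense_context(gene_id, genome, annotation, v$pos)
    if (!is.na(ctx$offset)) {
      alt_sense <- if (ctx$strand == "+") v$alt else comp_base(v$alt)
      alt_seq <- ctx$seq
      substr(alt_seq, ctx$offset, ctx$offset) <- alt_sense
      for (j in max(1L, ctx$offset - 2L):ctx$offset) {
        if (j + 2L > nchar(ctx$seq)) break
        if (substr(alt_seq, j, j + 2L) == "ATG" &&
            substr(ctx$seq, j, j + 2L) != "ATG")
          return(list(coding_effect = "start_gained", aa_change = ""))
      }
    }
  }
  list(coding_effect = "none", aa_change = "")
}

# Single-codon SNP consequence (fast route).
codon_snp_effect <- function(v, gene_id, genome, annotation) {
  cs <- gene_cds_seq(genome, annotation, gene_id)
  ref_genomic <- substr(genome[[v$chrom]], v$pos, v$pos)
  if (ref_genomic != v$ref)
    stop("reference mismatch at ", v$chrom, ":", v$pos, " (genome has ",
         ref_genomic, ", VCF says ", v$ref, ")")
  o <- match(v$pos, cs$genomic_pos)
  n_codons <- nchar(cs$seq) %/% 3L
  ci <- (o - 1L) %/% 3L + 1L
  within <- o - 3L * (ci - 1L)
  codon <- substr(cs$seq, 3L * ci - 2L, 3L * ci)
  alt_sense <- if (cs$strand == "+") v$alt else comp_base(v$alt)
  alt_codon <- codon
  substr(alt_codon, within, within) <- alt_sense
  aa_ref <- unname(Biostrings::GENETIC_CODE[codon])
  aa_alt <- unname(Biostrings::GENETIC_CODE[alt_codon])
  if (aa_ref == aa_alt)
    return(list(coding_effect = "synonymous", aa_change = ""))
  aa <- aa_change_label(aa_ref, ci, aa_alt)
  eff <- if (ci == 1L && aa_ref == "M") "start_lost"
  else if (aa_alt == "*") "stop_gained"
  else if (aa_ref == "*" && ci == n_codons) "stop_lost"
  else "nonsynonymous"
  list(coding_effect = eff, aa_change = aa)
}

#' Annotate variants: regions plus coding consequences
#'
#' The fast production route: vectorized region classification followed by
#' codon-level effect evaluation for the variants that need it.
#'
#' @inheritParams classify_region
#' @param genome named character vector of sequences.
#' @return Effect table: `chrom`, `pos`, `ref`, `alt`, `gene_id`, `region`,
#'   `coding_effect`, `aa_change`.
#' @examples
#' sim <- simulate_genome(sim_config(seed = 2, n_genes = 4))
#' vs <- simulate_variants(sim)
#' eff <- annotate_variants(vs$variants, sim$genome, sim$annotation)
#' table(eff$region)
#' @export
annotate_variants <- function(variants, genome, annotation, flank = 5000L,
                              splice_site_on = c("intron", "exon")) {
  splice_site_on <- match.arg(splice_site_on)
  cr <- classify_region(variants, annotation, chroms = names(genome),
                        flank = flank, splice_site_on = splice_site_on)
  cr$coding_effect <- "none"
  cr$aa_change <- ""
  needs <- which(cr$region %in% c("exon", "splice_site", "utr5"))
  for (i in needs) {
    eff <- coding_effect(cr[i, c("chrom", "pos", "ref", "alt")],
                         cr$gene_id[i], genome, annotation,
                         region = cr$region[i],
                         splice_site_on = splice_site_on)
    cr$coding_effect[i] <- eff$coding_effect
    cr$aa_change[i] <- eff$aa_change
  }
  cr
}

#' Transition/transversion ratio
#'
#' Counts A<->G and C<->T substitutions as transitions and all other SNP
#' substitutions as transversions; indels are excluded. With zero
#' transversions the ratio is undefined and `Inf` is returned as a flag.
#'
#' @param variants data frame with `ref` and `alt` columns.
#' @return The Ti/Tv ratio (or `Inf`).
#' @examples
#' titv(data.frame(ref = c("A", "C", "A"), alt = c("G", "T", "T"))) # 2
#' @export
titv <- function(variants) {
  snp <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L
  ref <- variants$ref[snp]; alt <- variants$alt[snp]
  ti <- (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
  n_ti <- sum(ti); n_tv <- sum(!ti)
  if (n_tv == 0L) return(Inf)
  n_ti / n_tv
}

#' Mutagenesis summary statistics
#'
#' Per-chromosome variant and mutated-gene counts, the signed indel
#' size-frequency histogram (insertions positive, deletions negative), the
#' heterozygous fraction, and region-class percentages (which sum to 100).
#'
#' @param variants data frame with `chrom`, `pos`, `ref`, `alt` and
#'   optionally `zygosity`.
#' @param effects effect table from [annotate_variants()].
#' @return A list with `per_chromosome`, `indel_histogram`, `het_fraction`,
#'   `region_percent`, `titv`.
#' @export
variant_summaries <- function(variants, effects) {
  if (!nrow(variants))
    return(list(per_chromosome = data.frame(chrom = character(0),
                                            n_variants = integer(0),
                                            n_mutated_genes = integer(0)),
                indel_histogram = data.frame(size = integer(0),
                                             count = integer(0)),
                het_fraction = 0, region_percent = numeric(0), titv = NA_real_))
  vtype <- mapply(variant_type, variants$ref, variants$alt,
                  USE.NAMES = FALSE)
  size <- abs(nchar(variants$alt) - nchar(variants$ref))
  signed <- ifelse(vtype == "insertion", size, -size)[vtype != "snp"]
  hist_tab <- as.data.frame(table(signed), stringsAsFactors = FALSE)
  indel_histogram <- data.frame(size = as.integer(hist_tab$signed),
                                count = as.integer(hist_tab$Freq))
  mut <- mutated_gene_set(effects)
  eff_mut <- effects[!is.na(effects$gene_id) & effects$gene_id %in% mut, ,
                     drop = FALSE]
  chroms <- sort(unique(variants$chrom))
  u <- unique(eff_mut[c("chrom", "gene_id")])
  per_chrom <- data.frame(
    chrom = chroms,
    n_variants = as.integer(table(factor(variants$chrom, levels = chroms))),
    n_mutated_genes = as.integer(table(factor(u$chrom, levels = chroms))),
    stringsAsFactors = FALSE)
  het_fraction <- if ("zygosity" %in% names(variants))
    mean(variants$zygosity == "het") else NA_real_
  region_percent <- 100 * table(effects$region) / nrow(effects)
  list(per_chromosome = per_chrom, indel_histogram = indel_histogram,
       het_fraction = het_fraction,
       region_percent = c(region_percent), titv = titv(variants))
}

#' Large-impact effect classes
#'
#' The coding-consequence classes regarded as having a large impact on
#' protein function.
#' @export
LARGE_IMPACT_CLASSES <- c("nonsynonymous", "stop_gained", "stop_lost",
                          "start_gained", "start_lost", "splice_acceptor",
                          "splice_donor", "codon_insertion",
                          "codon_deletion", "frameshift")

#' Set of mutated genes
#'
#' Genes with at least one variant effect in the given classes; each gene is
#' counted once regardless of how many qualifying variants hit it.
#'
#' @param effects effect table from [annotate_variants()].
#' @param classes effect classes that qualify (default: the large-impact
#'   classes; use `"nonsynonymous"` alone for a nonsynonymous-only set).
#' @return Character vector of gene ids, sorted.
#' @export
mutated_gene_set <- function(effects, classes = LARGE_IMPACT_CLASSES) {
  hit <- effects$coding_effect %in% classes & !is.na(effects$gene_id)
  sort(unique(effects$gene_id[hit]))
}
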