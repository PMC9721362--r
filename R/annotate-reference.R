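#' Reference variant annotation by exhaustive scan and full translation
#'
#' A deliberately simple, slow annotator used two ways: the synthetic-data
#' generator labels its variants with it (truth labels), and the test suite
#' uses it as the independent oracle for the fast annotator. Regions are
#' assigned by scanning every feature interval of every gene; coding
#' consequences of CDS SNPs are obtained by rebuilding the entire mutant
#' coding sequence, translating both proteins and diffing them.
#'
#' Conventions (shared with [annotate_variants()]): the classified position
#' is the variant's first affected base (the SNP base, the insertion anchor,
#' the first deleted base); region priority is CDS over splice site over
#' UTR over intron over gene flank over intergenic; flank assignment within
#' `flank` bp picks the nearest gene, ties broken by lexicographically
#' smaller gene id.
#'
#' @param variants data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param genome named character vector of sequences.
#' @param annotation a `gene_annotation` list.
#' @param flank flank width in bp (default 5000).
#' @param splice_site_on `"intron"` (first/last 2 bp of an intron; default)
#'   or `"exon"` (first/last 2 bp of an exon).
#' @return Data frame: `chrom`, `pos`, `ref`, `alt`, `gene_id`, `region`,
#'   `coding_effect`, `aa_change`; one row per variant-gene pair.
#' @export
annotate_variants_reference <- function(variants, genome, annotation,
                                        flank = 5000L,
                                        splice_site_on = c("intron", "exon")) {
  splice_site_on <- match.arg(splice_site_on)
  genes <- annotation$genes
  rows <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (!v$chrom %in% names(genome))
      stop("unplaced variant: chromosome '", v$chrom,
           "' absent from the annotation/genome")
    vtype <- variant_type(v$ref, v$alt)
    anchor <- if (vtype == "deletion") v$pos + 1L else v$pos
    cand <- genes[genes$chrom == v$chrom & genes$start <= anchor &
                    genes$end >= anchor, , drop = FALSE]
    if (nrow(cand) > 0L) {
      sub <- lapply(cand$gene_id, function(gid) {
        reference_effect_in_gene(v, vtype, anchor, gid, genome, annotation,
                                 splice_site_on)
      })
      rows[[i]] <- do.call(rbind, sub)
    } else {
      same <- genes[genes$chrom == v$chrom, , drop = FALSE]
      d <- ifelse(anchor < same$start, same$start - anchor,
                  anchor - same$end)
      near <- which(d >= 1L & d <= flank)
      if (length(near)) {
        j <- near[order(d[near], same$gene_id[near])][1L]
        g <- same[j, ]
        upstream_side <- anchor < g$start
        region <- if ((g$strand == "+") == upstream_side) "upstream_5kb"
        else "downstream_5kb"
        rows[[i]] <- effect_row(v, g$gene_id, region, "none", "")
      } else {
        rows[[i]] <- effect_row(v, NA_character_, "intergenic", "none", "")
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

effect_row <- function(v, gene_id, region, effect, aa) {
  data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
             gene_id = gene_id, region = region, coding_effect = effect,
             aa_change = aa, stringsAsFactors = FALSE)
}

variant_type <- function(ref, alt) {
  if (nchar(ref) == 1L && nchar(alt) == 1L) "snp"
  else if (nchar(alt) > nchar(ref)) "insertion"
  else "deletion"
}

in_any <- function(p, ints) nrow(ints) > 0L && any(p >= ints$start &
                                                     p <= ints$end)

# Region + effect of one variant inside one gene, reference route.
reference_effect_in_gene <- function(v, vtype, anchor, gid, genome,
                                     annotation, splice_site_on) {
  g <- annotation$genes[annotation$genes$gene_id == gid, ]
  cds <- gene_feature_intervals(annotation, gid, "CDS")
  utr5 <- gene_feature_intervals(annotation, gid, "five_prime_UTR")
  utr3 <- gene_feature_intervals(annotation, gid, "three_prime_UTR")
  introns <- gene_introns(annotation, gid)
  ss <- splice_windows(annotation, gid, g$strand, splice_site_on)

  splice_hit <- function() {
    if (in_any(anchor, ss$donor)) "splice_donor"
    else if (in_any(anchor, ss$acceptor)) "splice_acceptor"
    else NA_character_
  }

  if (splice_site_on == "exon") {
    # exon-anchored splice windows sit inside exons and must win over CDS,
    # otherwise the setting would never label anything
    sh <- splice_hit()
    if (!is.na(sh)) return(effect_row(v, gid, "splice_site", sh, ""))
  }
  if (in_any(anchor, cds)) {
    if (vtype == "snp") {
      eff <- translation_diff_effect(v, gid, genome, annotation)
      return(effect_row(v, gid, "exon", eff$effect, eff$aa))
    }
    size <- abs(nchar(v$alt) - nchar(v$ref))
    eff <- if (size %% 3L != 0L) "frameshift"
    else if (vtype == "insertion") "codon_insertion" else "codon_deletion"
    return(effect_row(v, gid, "exon", eff, ""))
  }
  sh <- splice_hit()
  if (!is.na(sh)) return(effect_row(v, gid, "splice_site", sh, ""))
  if (in_any(anchor, utr5)) {
    eff <- "none"
    if (vtype == "snp" && utr5_creates_atg_full(v, gid, genome, annotation))
      eff <- "start_gained"
    return(effect_row(v, gid, "utr5", eff, ""))
  }
  if (in_any(anchor, utr3))
    return(effect_row(v, gid, "utr3", "none", ""))
  if (in_any(anchor, introns))
    return(effect_row(v, gid, "intron", "none", ""))
  effect_row(v, gid, "intron", "none", "")
}

# Donor/acceptor 2-bp windows of a gene, genomic coordinates.
splice_windows <- function(annotation, gid, strand, splice_site_on) {
  introns <- gene_introns(annotation, gid)
  if (splice_site_on == "intron") {
    if (!nrow(introns))
      return(list(donor = introns, acceptor = introns))
    left <- data.frame(start = introns$start, end = introns$start + 1L)
    right <- data.frame(start = introns$end - 1L, end = introns$end)
    if (strand == "+") list(donor = left, acceptor = right)
    else list(donor = right, acceptor = left)
  } else {
    ex <- gene_feature_intervals(annotation, gid, "exon")
    if (nrow(ex) < 2L) {
      e0 <- data.frame(start = integer(0), end = integer(0))
      return(list(donor = e0, acceptor = e0))
    }
    # exon edges adjacent to an intron: all exon ends except the last, all
    # exon starts except the first (in genomic order)
    right_edge <- data.frame(start = ex$end[-nrow(ex)] - 1L,
                             end = ex$end[-nrow(ex)])
    left_edge <- data.frame(start = ex$start[-1L], end = ex$start[-1L] + 1L)
    if (strand == "+") list(donor = right_edge, acceptor = left_edge)
    else list(donor = left_edge, acceptor = right_edge)
  }
}

# Full-translation protein diff for a CDS SNP (reference oracle route).
translation_diff_effect <- function(v, gid, genome, annotation) {
  g <- annotation$genes[annotation$genes$gene_id == gid, ]
  cds <- gene_feature_intervals(annotation, gid, "CDS")
  chrom_seq <- genome[[v$chrom]]
  pieces <- substring(chrom_seq, cds$start, cds$end)
  plus_seq <- paste(pieces, collapse = "")
  plus_pos <- unlist(Map(seq.int, cds$start, cds$end), use.names = FALSE)
  off_plus <- match(v$pos, plus_pos)
  if (substr(plus_seq, off_plus, off_plus) != v$ref)
    stop("reference mismatch at ", v$chrom, ":", v$pos, " (expected ",
         substr(plus_seq, off_plus, off_plus), ", VCF says ", v$ref, ")")
  alt_plus <- plus_seq
  substr(alt_plus, off_plus, off_plus) <- v$alt
  if (g$strand == "+") {
    ref_cds <- plus_seq; alt_cds <- alt_plus
  } else {
    ref_cds <- revcomp(plus_seq); alt_cds <- revcomp(alt_plus)
  }
  p_ref <- translate_str(ref_cds)
  p_alt <- translate_str(alt_cds)
  if (identical(p_ref, p_alt))
    return(list(effect = "synonymous", aa = ""))
  aa_r <- strsplit(p_ref, "")[[1]]
  aa_a <- strsplit(p_alt, "")[[1]]
  i <- which(aa_r != aa_a)[1L]
  aa <- aa_change_label(aa_r[i], i, aa_a[i])
  eff <- if (i == 1L && aa_r[1L] == "M") "start_lost"
  else if (aa_a[i] == "*") "stop_gained"
  else if (aa_r[i] == "*") "stop_lost"
  else "nonsynonymous"
  list(effect = eff, aa = aa)
}

# Sense-strand 5' UTR sequence of a gene plus the first two CDS bases, and
# the sense offset of a genomic position within it.
utr5_sense_context <- function(gid, genome, annotation, pos) {
  g <- annotation$genes[annotation$genes$gene_id == gid, ]
  utr5 <- gene_feature_intervals(annotation, gid, "five_prime_UTR")
  cds <- gene_feature_intervals(annotation, gid, "CDS")
  chrom_seq <- genome[[g$chrom]]
  u_plus <- paste(substring(chrom_seq, utr5$start, utr5$end), collapse = "")
  u_pos <- unlist(Map(seq.int, utr5$start, utr5$end), use.names = FALSE)
  if (g$strand == "+") {
    first2 <- substr(chrom_seq, cds$start[1L], cds$start[1L] + 1L)
    seq <- paste0(u_plus, first2)
    off <- match(pos, u_pos)
  } else {
    last <- cds[nrow(cds), ]
    first2 <- revcomp(substr(chrom_seq, last$end - 1L, last$end))
    seq <- paste0(revcomp(u_plus), first2)
    off <- match(pos, rev(u_pos))
  }
  list(seq = seq, offset = off, strand = g$strand)
}

# Does a UTR5 SNP create a new ATG in any window overlapping the mutated
# base? (full-scan route)
utr5_creates_atg_full <- function(v, gid, genome, annotation) {
  ctx <- utr5_sense_context(gid, genome, annotation, v$pos)
  if (is.na(ctx$offset)) return(FALSE)
  alt_sense <- if (ctx$strand == "+") v$alt else comp_base(v$alt)
  alt_seq <- ctx$seq
  substr(alt_seq, ctx$offset, ctx$offset) <- alt_sense
  n <- nchar(ctx$seq)
  for (j in seq_len(max(0L, n - 2L))) {
    if (j > ctx$offset || j + 2L < ctx$offset) next
    if (substr(alt_seq, j, j + 2L) == "ATG" &&
        substr(ctx$seq, j, j + 2L) != "ATG") return(TRUE)
  }
  FALSE
}
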