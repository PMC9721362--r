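#' Genes overlapping DMRs
#'
#' A gene is assigned when its body or promoter (strand-aware, default
#' 2,000 bp upstream, the same convention as the CGI region) overlaps at
#' least one DMR by at least 1 bp.
#'
#' @param dmrs DMR table (`chrom`, `start`, `end`).
#' @param annotation a `gene_annotation` list.
#' @param promoter_bp promoter width in bp (default 2000).
#' @return Sorted character vector of gene ids.
#' @export
assign_dmr_genes <- function(dmrs, annotation, promoter_bp = 2000L) {
  genes <- annotation$genes
  dmrs <- dmrs[dmrs$chrom %in% genes$chrom, , drop = FALSE]
  if (!nrow(dmrs) || !nrow(genes)) return(character(0))
  start <- ifelse(genes$strand == "+", genes$start - promoter_bp,
                  genes$start)
  end <- ifelse(genes$strand == "+", genes$end, genes$end + promoter_bp)
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(pmax(1L, start), end))
  dd <- GenomicRanges::GRanges(dmrs$chrom,
                               IRanges::IRanges(dmrs$start, dmrs$end))
  hits <- GenomicRanges::findOverlaps(gg, dd)
  sort(unique(genes$gene_id[S4Vectors::queryHits(hits)]))
}

#' Three-way omics gene-set integration
#'
#' Computes all seven Venn cells over the variant (R), transcriptome (T)
#' and methylome (M) gene sets, plus the pairwise and triple intersections
#' and the percentage of DEGs also carrying a qualifying variant.
#'
#' @param set_R gene ids with large-impact (or nonsynonymous) variants.
#' @param set_T DEG ids.
#' @param set_M ids of genes overlapping DMRs.
#' @return A list of class `integration_report`: `sets`, `intersections`
#'   (`RT`, `TM`, `RM`, `RTM`), `venn_cells` (the 7 disjoint cells:
#'   `R_only`, `T_only`, `M_only`, `RT_only`, `TM_only`, `RM_only`,
#'   `RTM`), `counts`, and `pct_T_with_R`.
#' @examples
#' rep <- overlap_sets(c("g1", "g2", "g3"), c("g2", "g3", "g4"), "g3")
#' rep$intersections$RTM  # "g3"
#' @export
overlap_sets <- function(set_R, set_T, set_M) {
  R <- sort(unique(as.character(set_R)))
  T_ <- sort(unique(as.character(set_T)))
  M <- sort(unique(as.character(set_M)))
  RT <- intersect(R, T_); TM <- intersect(T_, M); RM <- intersect(R, M)
  RTM <- intersect(RT, M)
  cells <- list(
    R_only = setdiff(R, union(T_, M)),
    T_only = setdiff(T_, union(R, M)),
    M_only = setdiff(M, union(R, T_)),
    RT_only = setdiff(RT, M),
    TM_only = setdiff(TM, R),
    RM_only = setdiff(RM, T_),
    RTM = RTM)
  structure(list(
    sets = list(R = R, T = T_, M = M),
    intersections = list(RT = RT, TM = TM, RM = RM, RTM = RTM),
    venn_cells = cells,
    counts = vapply(cells, length, integer(1)),
    pct_T_with_R = if (length(T_)) 100 * length(RT) / length(T_) else
      NA_real_), class = "integration_report")
}

#' Candidate-gene report over the omics intersections
#'
#' One row per gene found in at least two omics layers, with its
#' classification (R vs T, T vs M, R vs M, or R vs T vs M), both
#' normalized expression values, fold change, p-values and a functional
#' annotation passthrough. Genes without expression data carry `NA`.
#'
#' @param report an `integration_report` from [overlap_sets()].
#' @param deg_results DE table from [run_deg()].
#' @param annotations optional named character vector of functional
#'   descriptions per gene id.
#' @return Data frame sorted by classification then gene id:
#'   `classification`, `gene_id`, `expr_control`, `expr_mutant`, `log2fc`,
#'   `pvalue`, `padj`, `annotation`.
#' @export
candidate_report <- function(report, deg_results, annotations = NULL) {
  ints <- report$intersections
  cls <- c("R vs T", "T vs M", "R vs M", "R vs T vs M")
  members <- list(setdiff(ints$RT, ints$RTM), setdiff(ints$TM, ints$RTM),
                  setdiff(ints$RM, ints$RTM), ints$RTM)
  rows <- list()
  for (i in seq_along(cls)) {
    for (gid in members[[i]]) {
      j <- match(gid, deg_results$gene_id)
      rows[[length(rows) + 1L]] <- data.frame(
        classification = cls[i], gene_id = gid,
        expr_control = if (!is.na(j)) deg_results$fpkm_control[j] else
          NA_real_,
        expr_mutant = if (!is.na(j)) deg_results$fpkm_mutant[j] else
          NA_real_,
        log2fc = if (!is.na(j)) deg_results$log2fc[j] else NA_real_,
        pvalue = if (!is.na(j)) deg_results$pvalue[j] else NA_real_,
        padj = if (!is.na(j)) deg_results$padj[j] else NA_real_,
        annotation = if (!is.null(annotations) && gid %in%
                         names(annotations)) annotations[[gid]] else
                           NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(classification = character(0), gene_id = character(0),
               expr_control = numeric(0), expr_mutant = numeric(0),
               log2fc = numeric(0), pvalue = numeric(0), padj = numeric(0),
               annotation = character(0), stringsAsFactors = FALSE)
  out <- out[order(match(out$classification, cls), out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
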