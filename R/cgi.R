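#' Promoter-to-3'UTR region of a gene
#'
#' Strand-aware interval from `promoter_bp` upstream of the transcription
#' start to the end of the 3' UTR (the gene end when no UTR is annotated),
#' clipped to the chromosome.
#'
#' @param gene one-row data frame with `chrom`, `strand`, `start`, `end`.
#' @param chrom_length chromosome length in bp.
#' @param promoter_bp promoter width (default 2000).
#' @return List with `start` and `end` (1-based inclusive).
#' @examples
#' g <- data.frame(chrom = "c", strand = "+", start = 10001, end = 13000)
#' gene_region(g, 2e4)  # 8001..13000
#' @export
gene_region <- function(gene, chrom_length, promoter_bp = 2000L) {
  if (gene$strand == "+") {
    start <- gene$start - promoter_bp
    end <- gene$end
  } else {
    start <- gene$start
    end <- gene$end + promoter_bp
  }
  list(start = max(1L, as.integer(start)),
       end = min(as.integer(chrom_length), as.integer(end)))
}

#' Predict CpG islands in a sequence
#'
#' Gardiner-Garden & Frommer style scan: a `window`-bp window slides by
#' `shift` bp; windows with GC percentage at least `min_gc` and observed/
#' expected CpG ratio at least `min_oe` (expected = countC * countG /
#' window length; observed = CG dinucleotides fully inside the window) are
#' merged where they overlap, and each merged region is reported if it is
#' at least `min_length` bp long and itself satisfies both thresholds as a
#' whole. Ns count toward length but not toward C/G.
#'
#' @param sequence a character string over A/C/G/T/N.
#' @param window,shift,min_gc,min_oe,min_length scan parameters (defaults
#'   100, 1, 50, 0.6, 200).
#' @return Data frame: `start`, `end`, `length`, `gc_percent`,
#'   `obs_exp_cpg` (1-based coordinates within `sequence`).
#' @examples
#' isl <- find_cgis(strrep("CG", 150))
#' isl$length     # 300
#' isl$obs_exp_cpg  # ~2
#' @export
find_cgis <- function(sequence, window = 100L, shift = 1L, min_gc = 50,
                      min_oe = 0.6, min_length = 200L) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), gc_percent = numeric(0),
                      obs_exp_cpg = numeric(0))
  n <- nchar(sequence)
  if (n < window) return(empty)
  chars <- strsplit(sequence, "")[[1]]
  isC <- as.integer(chars == "C")
  isG <- as.integer(chars == "G")
  isCG <- as.integer(chars[-n] == "C" & chars[-1] == "G")
  cumC <- c(0L, cumsum(isC))
  cumG <- c(0L, cumsum(isG))
  cumCG <- c(0L, cumsum(isCG))
  starts <- seq.int(1L, n - window + 1L, by = shift)
  ends <- starts + window - 1L
  nC <- cumC[ends + 1L] - cumC[starts]
  nG <- cumG[ends + 1L] - cumG[starts]
  # CG dinucleotides fully inside [start, end]: start index in [start, end-1]
  nCG <- cumCG[ends] - cumCG[starts]
  gc <- 100 * (nC + nG) / window
  expected <- nC * nG / window
  oe <- ifelse(expected > 0, nCG / expected, 0)
  pass <- gc >= min_gc & oe >= min_oe
  if (!any(pass)) return(empty)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    "s", IRanges::IRanges(starts[pass], ends[pass])))
  reg <- data.frame(start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr))
  reg$length <- reg$end - reg$start + 1L
  reg$gc_percent <- 100 * (cumC[reg$end + 1L] - cumC[reg$start] +
                             cumG[reg$end + 1L] - cumG[reg$start]) /
    reg$length
  rC <- cumC[reg$end + 1L] - cumC[reg$start]
  rG <- cumG[reg$end + 1L] - cumG[reg$start]
  rCG <- cumCG[reg$end] - cumCG[reg$start]
  rExp <- rC * rG / reg$length
  reg$obs_exp_cpg <- ifelse(rExp > 0, rCG / rExp, 0)
  keep <- reg$length >= min_length & reg$gc_percent >= min_gc &
    reg$obs_exp_cpg >= min_oe
  out <- reg[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict CpG islands for each gene's promoter-to-3'UTR region
#'
#' @param annotation a `gene_annotation` list.
#' @param genome named character vector of sequences.
#' @param gene_ids genes to scan (default: all).
#' @param promoter_bp promoter width (default 2000).
#' @param ... passed to [find_cgis()].
#' @return Data frame of islands in chromosome coordinates: `gene_id`,
#'   `chrom`, `start`, `end`, `length`, `gc_percent`, `obs_exp_cpg`.
#' @export
find_gene_cgis <- function(annotation, genome,
                           gene_ids = annotation$genes$gene_id,
                           promoter_bp = 2000L, ...) {
  rows <- lapply(gene_ids, function(gid) {
    g <- annotation$genes[annotation$genes$gene_id == gid, ]
    reg <- gene_region(g, nchar(genome[[g$chrom]]), promoter_bp)
    isl <- find_cgis(substr(genome[[g$chrom]], reg$start, reg$end), ...)
    if (!nrow(isl)) return(NULL)
    data.frame(gene_id = gid, chrom = g$chrom,
               start = isl$start + reg$start - 1L,
               end = isl$end + reg$start - 1L, length = isl$length,
               gc_percent = isl$gc_percent, obs_exp_cpg = isl$obs_exp_cpg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), gc_percent = numeric(0),
                      obs_exp_cpg = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Count methylated sites inside a CpG island
#'
#' Counts cytosines called methylated within `[start, end]`, per context,
#' for each sample.
#'
#' @param island one-row data frame with `chrom`, `start`, `end`.
#' @param calls_list named list of called site tables ([call_sites()]).
#' @return Matrix with one row per sample and columns CG, CHG, CHH.
#' @export
count_meth_in_cgi <- function(island, calls_list) {
  t(vapply(calls_list, function(cl) {
    sel <- !is.na(cl$methylated) & cl$methylated &
      cl$chrom == island$chrom & cl$pos >= island$start &
      cl$pos <= island$end
    vapply(c(CG = "CG", CHG = "CHG", CHH = "CHH"),
           function(cx) sum(sel & cl$context == cx), numeric(1))
  }, numeric(3)))
}

#' Classify a DEG's methylation-expression pattern
#'
#' `opposite` when expression and CGI methylation move in opposite
#' directions (up-regulated with less methylation or down-regulated with
#' more), `flat` when the methylation difference is zero, otherwise
#' `concordant`.
#'
#' @param deg one-row data frame with `gene_id`, `status` (`up`/`down`) and
#'   `log2fc`.
#' @param meth_delta CGI methylated-site count (or level) difference,
#'   mutant minus control.
#' @return List with `gene_id`, `deg_status`, `cgi_meth_delta`, `pattern`.
#' @export
classify_pattern <- function(deg, meth_delta) {
  if (!deg$status %in% c("up", "down"))
    stop("not applicable: pattern classification requires a called DEG")
  pattern <- if (meth_delta == 0) "flat"
  else if (sign(deg$log2fc) * sign(meth_delta) == -1) "opposite"
  else "concordant"
  list(gene_id = deg$gene_id, deg_status = as.character(deg$status),
       cgi_meth_delta = meth_delta, pattern = pattern)
}

#' Methylation-expression pattern table over all CGI-bearing DEGs
#'
#' For every called DEG with at least one predicted island, sums the
#' methylated-site difference (mutant minus control) across its islands
#' and classifies the pattern.
#'
#' @param deg_results DE table from [run_deg()].
#' @param islands island table from [find_gene_cgis()].
#' @param calls_list named list of two called site tables, in the order
#'   control then mutant.
#' @return Data frame: `gene_id`, `deg_status`, `cgi_meth_delta`,
#'   `pattern`.
#' @export
cgi_pattern_table <- function(deg_results, islands, calls_list) {
  stopifnot(length(calls_list) == 2L)
  degs <- deg_results[deg_results$status %in% c("up", "down"), ,
                      drop = FALSE]
  degs <- degs[degs$gene_id %in% islands$gene_id, , drop = FALSE]
  rows <- lapply(seq_len(nrow(degs)), function(i) {
    gid <- degs$gene_id[i]
    isl <- islands[islands$gene_id == gid, , drop = FALSE]
    delta <- 0
    for (j in seq_len(nrow(isl))) {
      cnt <- count_meth_in_cgi(isl[j, ], calls_list)
      delta <- delta + sum(cnt[2L, ]) - sum(cnt[1L, ])
    }
    as.data.frame(classify_pattern(degs[i, ], delta),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), deg_status = character(0),
                      cgi_meth_delta = numeric(0), pattern = character(0),
                      stringsAsFactors = FALSE)
  out
}
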