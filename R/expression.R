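#' FPKM from counts
#'
#' `count * 1e9 / (length_bp * library_total)`: fragments per kilobase of
#' gene model per million mapped reads.
#'
#' @param count read counts.
#' @param length_bp gene lengths in bp.
#' @param library_total total mapped reads of the library.
#' @return Numeric vector of FPKM values.
#' @export
fpkm <- function(count, length_bp, library_total) {
  count * 1e9 / (length_bp * library_total)
}

#' TMM scaling factor between two libraries
#'
#' The single trimmed-mean-of-M-values factor relating the mutant library
#' to the control (reference) library, with the standard trims (30% on
#' log-ratios, 5% on absolute intensity). Equal libraries give 1; a pure
#' depth shift also gives 1, the depth itself being carried by the library
#' totals. The factor is applied by scaling the mutant library's effective
#' total.
#'
#' @param counts_control,counts_mutant integer count vectors over the same
#'   genes.
#' @return A positive scalar factor.
#' @export
scaling_factor <- function(counts_control, counts_mutant) {
  if (sum(counts_control) == 0 || sum(counts_mutant) == 0)
    stop("no signal: one library has all-zero counts")
  keep <- counts_control > 0 | counts_mutant > 0
  if (sum(counts_control > 0 & counts_mutant > 0) < 2L)
    stop("need at least 2 genes with nonzero counts in both libraries")
  m <- cbind(control = counts_control[keep], mutant = counts_mutant[keep])
  f <- edgeR::calcNormFactors(m, method = "TMM", refColumn = 1L)
  unname(f[2L] / f[1L])
}

#' Log2 fold change with conditional pseudocount
#'
#' `log2((mutant + p) / (control + p))` where the pseudocount `p` is
#' applied only when either value is zero.
#'
#' @param control_value,mutant_value non-negative expression values.
#' @param pseudocount pseudocount `p` (default 0.1).
#' @return Numeric vector of log2 fold changes (mutant over control).
#' @examples
#' round(log2fc(21.18, 74.94), 2)  # 1.82
#' round(log2fc(71.62, 3.25), 2)   # -4.46
#' @export
log2fc <- function(control_value, mutant_value, pseudocount = 0.1) {
  n <- max(length(control_value), length(mutant_value))
  cv <- rep_len(control_value, n); mv <- rep_len(mutant_value, n)
  zero <- cv == 0 | mv == 0
  if (any(zero & pseudocount == 0))
    stop("undefined fold change: zero value with pseudocount 0")
  p <- ifelse(zero, pseudocount, 0)
  log2((mv + p) / (cv + p))
}

#' Exact conditional binomial test for no-replicate DE
#'
#' With one library per condition, a gene's mutant count given its total
#' `k = count_control + count_mutant` is, under the null of equal relative
#' expression, binomial with success probability
#' `n_mutant_total / (n_control_total + n_mutant_total)` (effective,
#' TMM-scaled totals). The two-sided p-value is
#' `min(1, 2 * min(lower tail, upper tail))`, computed exactly; genes with
#' `k = 0` get p = 1 by convention.
#'
#' @param count_control,count_mutant per-gene counts (vectors).
#' @param n_control_total,n_mutant_total (effective) library totals.
#' @return Numeric vector of two-sided p-values.
#' @examples
#' deg_test(0, 10, 1e6, 1e6)  # 2 * 0.5^10
#' deg_test(5, 5, 1e6, 1e6)   # 1
#' @export
deg_test <- function(count_control, count_mutant, n_control_total,
                     n_mutant_total) {
  if (n_control_total <= 0 || n_mutant_total <= 0)
    stop("library totals must be positive")
  k <- count_control + count_mutant
  pi0 <- n_mutant_total / (n_control_total + n_mutant_total)
  lower <- pbinom(count_mutant, k, pi0)
  upper <- pbinom(count_mutant - 1, k, pi0, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lower, upper))
  p[k == 0] <- 1
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with monotonicity enforcement, order-preserving.
#'
#' @param pvalues vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed genes
#'
#' `up` when adjusted p is below `padj_threshold` and log2 fold change at
#' least `lfc_threshold`; `down` with log2 fold change at most minus the
#' threshold; otherwise `ns`. The three sets partition the input.
#'
#' @param results data frame with `padj` and `log2fc` columns.
#' @param padj_threshold adjusted-p threshold (default 0.005).
#' @param lfc_threshold absolute log2 fold-change threshold (default 1,
#'   i.e. two-fold).
#' @return The input with a `status` factor column added.
#' @export
call_degs <- function(results, padj_threshold = 0.005, lfc_threshold = 1) {
  status <- rep("ns", nrow(results))
  sig <- results$padj < padj_threshold
  status[sig & results$log2fc >= lfc_threshold] <- "up"
  status[sig & results$log2fc <= -lfc_threshold] <- "down"
  results$status <- factor(status, levels = c("up", "down", "ns"))
  results
}

#' No-replicate differential-expression analysis of a two-library table
#'
#' The full DE stage: drops genes with zero counts in both libraries,
#' computes the TMM scaling factor (control as reference) and effective
#' library totals, FPKM per library, the exact conditional binomial test
#' per gene, BH adjustment, fold changes on normalized expression, and the
#' final up/down/ns call.
#'
#' @param counts count table (`gene_id`, `length_bp`, `count_control`,
#'   `count_mutant`).
#' @param padj_threshold,lfc_threshold DE-call thresholds (defaults 0.005
#'   and 1).
#' @param pseudocount pseudocount for zero-value fold changes (default 0.1).
#' @return Data frame: `gene_id`, `fpkm_control`, `fpkm_mutant`, `log2fc`,
#'   `pvalue`, `padj`, `status`. The attribute `scaling` records the TMM
#'   factor and effective totals.
#' @examples
#' cfg <- sim_config(seed = 5, n_genes = 300)
#' cts <- simulate_counts(300L, cfg)
#' res <- run_deg(cts$counts)
#' table(res$status)
#' @export
run_deg <- function(counts, padj_threshold = 0.005, lfc_threshold = 1,
                    pseudocount = 0.1) {
  keep <- counts$count_control + counts$count_mutant > 0
  x <- counts[keep, , drop = FALSE]
  f <- scaling_factor(x$count_control, x$count_mutant)
  # split the factor symmetrically (product-one normalization), so that
  # swapping the two libraries mirrors every normalized quantity exactly
  total_c <- sum(x$count_control) / sqrt(f)
  total_m <- sum(x$count_mutant) * sqrt(f)
  x$fpkm_control <- fpkm(x$count_control, x$length_bp, total_c)
  x$fpkm_mutant <- fpkm(x$count_mutant, x$length_bp, total_m)
  x$log2fc <- log2fc(x$fpkm_control, x$fpkm_mutant, pseudocount)
  x$pvalue <- deg_test(x$count_control, x$count_mutant, total_c, total_m)
  x$padj <- bh_adjust(x$pvalue)
  x <- call_degs(x, padj_threshold, lfc_threshold)
  out <- x[, c("gene_id", "fpkm_control", "fpkm_mutant", "log2fc",
               "pvalue", "padj", "status")]
  rownames(out) <- NULL
  attr(out, "scaling") <- list(tmm_factor = f, effective_total_control =
                                 total_c, effective_total_mutant = total_m)
  out
}
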