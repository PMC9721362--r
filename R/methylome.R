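#' Enumerate all cytosines of a genome with their context
#'
#' Walks both strands of every sequence and reports each cytosine with its
#' methylation context, read from the two bases downstream on the cytosine's
#' own strand: CG if the next base is G; CHG if the next is H (A/C/T) and
#' the second-next G; otherwise CHH. Cytosines within 2 bp of a sequence end
#' whose context is undeterminable fall back to CHH and are flagged.
#'
#' @param genome named character vector of sequences.
#' @param chroms optional subset of sequence names.
#' @return Data frame: `chrom`, `pos` (1-based), `strand`, `context`,
#'   `trinucleotide`, `context_flagged`.
#' @export
cytosine_sites <- function(genome, chroms = names(genome)) {
  out <- lapply(chroms, function(ch) {
    chars <- strsplit(genome[[ch]], "")[[1]]
    L <- length(chars)
    pad <- function(x) ifelse(is.na(x), "N", x)
    pC <- which(chars == "C")
    n1 <- pad(chars[pC + 1L]); n2 <- pad(chars[pC + 2L])
    ctx_p <- ifelse(n1 == "G", "CG", ifelse(n2 == "G", "CHG", "CHH"))
    flag_p <- (pC + 1L > L) | (n1 != "G" & pC + 2L > L)
    tri_p <- paste0("C", n1, n2)
    pG <- which(chars == "G")
    # negative/zero subscripts would silently drop elements; guard them
    m1 <- pad(ifelse(pG - 1L >= 1L, chars[pmax(pG - 1L, 1L)], NA))
    m2 <- pad(ifelse(pG - 2L >= 1L, chars[pmax(pG - 2L, 1L)], NA))
    ctx_m <- ifelse(m1 == "C", "CG", ifelse(m2 == "C", "CHG", "CHH"))
    flag_m <- (pG - 1L < 1L) | (m1 != "C" & pG - 2L < 1L)
    tri_m <- paste0("C", unname(COMPLEMENT[m1]), unname(COMPLEMENT[m2]))
    df <- data.frame(
      chrom = ch,
      pos = c(pC, pG),
      strand = rep(c("+", "-"), c(length(pC), length(pG))),
      context = c(ctx_p, ctx_m),
      trinucleotide = c(tri_p, tri_m),
      context_flagged = c(flag_p, flag_m),
      stringsAsFactors = FALSE)
    df[order(df$pos, df$strand), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Context of single cytosines
#'
#' @param genome named character vector of sequences.
#' @param chrom,pos,strand parallel vectors locating cytosines (1-based;
#'   strand `"+"` or `"-"`).
#' @return Character vector of contexts (`CG`, `CHG`, `CHH`).
#' @examples
#' context_of(c(x = "ACGT"), "x", 2, "+")   # CG
#' context_of(c(x = "ACAGT"), "x", 2, "+")  # CHG
#' @export
context_of <- function(genome, chrom, pos, strand) {
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  strand <- rep_len(strand, n)
  vapply(seq_len(n), function(i) {
    s <- genome[[chrom[i]]]
    L <- nchar(s)
    p <- pos[i]
    base <- substr(s, p, p)
    if (strand[i] == "+") {
      if (base != "C")
        stop("not a cytosine: ", chrom[i], ":", p, " (+) is ", base)
      b1 <- if (p + 1L <= L) substr(s, p + 1L, p + 1L) else "N"
      b2 <- if (p + 2L <= L) substr(s, p + 2L, p + 2L) else "N"
    } else {
      if (base != "G")
        stop("not a cytosine: ", chrom[i], ":", p, " (-) is ",
             comp_base(base))
      b1 <- if (p - 1L >= 1L) comp_base(substr(s, p - 1L, p - 1L)) else "N"
      b2 <- if (p - 2L >= 1L) comp_base(substr(s, p - 2L, p - 2L)) else "N"
    }
    if (b1 == "G") "CG" else if (b2 == "G") "CHG" else "CHH"
  }, character(1))
}

#' Estimate the bisulfite non-conversion rate from a spike-in control
#'
#' On a sequence that is unmethylated by construction, every methylated read
#' is a conversion failure, so the rate is the total methylated read count
#' over the total read count.
#'
#' @param control_sites cytosine table (columns `meth`, `unmeth`) restricted
#'   to the unmethylated control sequence.
#' @param source identifier of the control sequence (bookkeeping only).
#' @return List with `rate`, `n_reads_used`, `source`.
#' @export
estimate_nonconversion <- function(control_sites,
                                   source = "control_unmethylated") {
  total <- sum(control_sites$meth) + sum(control_sites$unmeth)
  if (total == 0)
    stop("cannot estimate non-conversion: zero coverage on the control")
  r <- sum(control_sites$meth) / total
  if (r >= 0.05)
    stop("implausible non-conversion rate ", signif(r, 3),
         " (>= 0.05); check that the control sequence is unmethylated")
  list(rate = r, n_reads_used = total, source = source)
}

#' Correct a methylation level for bisulfite non-conversion
#'
#' Applies `(ml - r) / (1 - r)`, clamped to `[0, 1]`: the identity at r = 0,
#' zero at `ml = r`, and fixed point 1 at `ml = 1`.
#'
#' @param ml raw methylation level(s) in `[0, 1]`.
#' @param r non-conversion rate in `[0, 1)`.
#' @return Corrected methylation level(s).
#' @examples
#' correct_ml(0.25, 0.0004) # 0.2497
#' @export
correct_ml <- function(ml, r) {
  if (any(r >= 1)) stop("invalid non-conversion rate: r must be < 1")
  clamp((ml - r) / (1 - r), 0, 1)
}

#' Call methylated cytosines with an exact binomial test
#'
#' Each site's methylated read count is modelled as binomial over its
#' coverage with success rate equal to the non-conversion rate `r`; the
#' p-value is the exact upper tail (probability of at least the observed
#' methylated count under non-conversion noise alone). Sites at or above
#' `min_coverage` are tested; p-values are BH-adjusted across tested sites
#' and sites with adjusted p below `fdr` are called methylated.
#'
#' @param sites cytosine table with columns `meth` and `unmeth` (and
#'   typically `chrom`, `pos`, `strand`, `context`).
#' @param r non-conversion rate.
#' @param min_coverage minimum coverage for testing (default 5).
#' @param fdr FDR threshold for the methylated call (default 0.05).
#' @return The input with columns added: `coverage`, `ml_raw`,
#'   `ml_corrected`, `pvalue`, `padj`, `methylated` (NA where coverage is
#'   below `min_coverage`). The attribute `qc` counts tested and excluded
#'   sites.
#' @export
call_sites <- function(sites, r, min_coverage = 5L, fdr = 0.05) {
  cov <- sites$meth + sites$unmeth
  sites$coverage <- cov
  sites$ml_raw <- ifelse(cov > 0, sites$meth / cov, NA_real_)
  sites$ml_corrected <- NA_real_
  sites$ml_corrected[cov > 0] <- correct_ml(sites$ml_raw[cov > 0], r)
  tested <- cov >= min_coverage
  p <- rep(NA_real_, nrow(sites))
  p[tested] <- pbinom(sites$meth[tested] - 1, cov[tested], r,
                      lower.tail = FALSE)
  sites$pvalue <- p
  sites$padj <- NA_real_
  sites$padj[tested] <- p.adjust(p[tested], method = "BH")
  sites$methylated <- ifelse(tested, sites$padj < fdr, NA)
  attr(sites, "qc") <- list(n_tested = sum(tested),
                            n_excluded = sum(!tested))
  sites
}

#' Aggregate cytosine counts in sliding windows
#'
#' Windows of `window` bp slide by `step` bp, starting at 1, 1+step,
#' 1+2*step, ...; the grid stops with the first window that reaches the
#' chromosome end (a 4,200 bp chromosome gives starts 1, 601, 1201), and
#' that last window is truncated at the chromosome end. Each window sums methylated and unmethylated reads (total and per
#' context) over the cytosines it covers; windows with no covered cytosine
#' are omitted.
#'
#' @param sites cytosine table with `chrom`, `pos`, `meth`, `unmeth`,
#'   `context`.
#' @param chrom_lengths named vector of sequence lengths.
#' @param window window size in bp (default 3000).
#' @param step step size in bp (default 600).
#' @return Data frame keyed by `chrom`, `start`, `end` with per-context and
#'   total read sums, `n_sites` (covered cytosines) and `ml` (summed meth /
#'   summed total). Attributes `window`/`step` record the grid.
#' @export
make_windows <- function(sites, chrom_lengths, window = 3000L,
                         step = 600L) {
  sites <- sites[(sites$meth + sites$unmeth) > 0, , drop = FALSE]
  n_off <- as.integer(ceiling(window / step))
  pieces <- lapply(seq_len(n_off) - 1L, function(k) {
    i <- (sites$pos - 1L) %/% step + 1L - k
    offset_in <- (sites$pos - 1L) %% step + k * step
    ok <- i >= 1L & offset_in < window
    data.frame(chrom = sites$chrom[ok], win = i[ok],
               context = sites$context[ok], meth = sites$meth[ok],
               unmeth = sites$unmeth[ok], stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, pieces)
  n_win <- pmax(ceiling((chrom_lengths - window) / step) + 1, 1)
  long <- long[long$win <= n_win[long$chrom], , drop = FALSE]
  if (!nrow(long)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_sites = integer(0), ml = numeric(0))
    attr(out, "window") <- window; attr(out, "step") <- step
    return(out)
  }
  key <- paste(long$chrom, long$win, sep = "\r")
  agg <- function(vals) rowsum(vals, key, reorder = TRUE)
  meth_tot <- agg(long$meth)
  unmeth_tot <- agg(long$unmeth)
  n_sites <- agg(rep(1L, nrow(long)))
  per_ctx <- lapply(c(CG = "CG", CHG = "CHG", CHH = "CHH"), function(cx) {
    sel <- long$context == cx
    m <- rowsum(long$meth * sel, key, reorder = TRUE)
    u <- rowsum(long$unmeth * sel, key, reorder = TRUE)
    list(m = m, u = u)
  })
  ks <- strsplit(rownames(meth_tot), "\r", fixed = TRUE)
  chrom <- vapply(ks, `[`, character(1), 1L)
  win <- as.integer(vapply(ks, `[`, character(1), 2L))
  start <- (win - 1L) * step + 1L
  end <- pmin(start + window - 1L, unname(chrom_lengths[chrom]))
  out <- data.frame(
    chrom = chrom, start = start, end = end,
    n_sites = as.integer(n_sites[, 1L]),
    meth = as.numeric(meth_tot[, 1L]), unmeth = as.numeric(unmeth_tot[, 1L]),
    meth_cg = as.numeric(per_ctx$CG$m[, 1L]),
    unmeth_cg = as.numeric(per_ctx$CG$u[, 1L]),
    meth_chg = as.numeric(per_ctx$CHG$m[, 1L]),
    unmeth_chg = as.numeric(per_ctx$CHG$u[, 1L]),
    meth_chh = as.numeric(per_ctx$CHH$m[, 1L]),
    unmeth_chh = as.numeric(per_ctx$CHH$u[, 1L]),
    stringsAsFactors = FALSE)
  out$ml <- out$meth / (out$meth + out$unmeth)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window") <- window
  attr(out, "step") <- step
  out
}

#' Detect differentially methylated regions between two samples
#'
#' On the shared window grid, each window's (methylated, unmethylated) read
#' sums are compared between samples with a two-sided Fisher exact test;
#' p-values are BH-adjusted across windows. Significant windows (adjusted
#' p below `fdr`, absolute methylation-level difference at least
#' `min_delta`, at least `min_sites` covered cytosines in both samples)
#' that overlap or abut are merged, and each merged region is trimmed to
#' its outermost covered cytosine, so reported DMRs can be much shorter
#' than one window.
#'
#' @param windows_control,windows_mutant window tables from
#'   [make_windows()], built on the same grid.
#' @param sites_control,sites_mutant the cytosine tables the windows were
#'   built from (used for trimming and region-level statistics).
#' @param fdr FDR threshold (default 0.05).
#' @param min_delta minimum absolute methylation-level difference
#'   (default 0.1).
#' @param min_sites minimum covered cytosines (default 3).
#' @return Data frame of DMRs: `chrom`, `start`, `end`, `length`,
#'   `n_sites`, `ml_control`, `ml_mutant`, `delta_ml` (mutant minus
#'   control), `pvalue`, `padj`, `direction` (`hyper`/`hypo`).
#' @export
call_dmrs <- function(windows_control, windows_mutant,
                      sites_control, sites_mutant,
                      fdr = 0.05, min_delta = 0.1, min_sites = 3L) {
  for (a in c("window", "step")) {
    if (!identical(attr(windows_control, a), attr(windows_mutant, a)))
      stop("grid mismatch: control and mutant windows were built with ",
           "different ", a, " sizes")
  }
  key_c <- paste(windows_control$chrom, windows_control$start)
  key_m <- paste(windows_mutant$chrom, windows_mutant$start)
  shared <- intersect(key_c, key_m)
  wc <- windows_control[match(shared, key_c), , drop = FALSE]
  wm <- windows_mutant[match(shared, key_m), , drop = FALSE]
  n <- nrow(wc)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      n_sites = integer(0), ml_control = numeric(0),
                      ml_mutant = numeric(0), delta_ml = numeric(0),
                      pvalue = numeric(0), padj = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE)
  if (!n) return(empty)
  p <- vapply(seq_len(n), function(i) {
    m <- matrix(c(wc$meth[i], wc$unmeth[i], wm$meth[i], wm$unmeth[i]), 2L)
    fisher.test(m)$p.value
  }, numeric(1))
  padj <- p.adjust(p, method = "BH")
  delta <- wm$ml - wc$ml
  sig <- padj < fdr & abs(delta) >= min_delta &
    pmin(wc$n_sites, wm$n_sites) >= min_sites
  if (!any(sig)) return(empty)
  sw <- wc[sig, c("chrom", "start", "end")]
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    sw$chrom, IRanges::IRanges(sw$start, sw$end)), min.gapwidth = 1L)
  merged <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                       start = GenomicRanges::start(gr),
                       end = GenomicRanges::end(gr),
                       stringsAsFactors = FALSE)
  cov_c <- sites_control[(sites_control$meth + sites_control$unmeth) > 0, ]
  cov_m <- sites_mutant[(sites_mutant$meth + sites_mutant$unmeth) > 0, ]
  rows <- lapply(seq_len(nrow(merged)), function(i) {
    reg <- merged[i, ]
    in_reg <- function(s) s$chrom == reg$chrom & s$pos >= reg$start &
      s$pos <= reg$end
    sc <- cov_c[in_reg(cov_c), ]
    sm <- cov_m[in_reg(cov_m), ]
    both <- intersect(paste(sc$pos, sc$strand), paste(sm$pos, sm$strand))
    pos_all <- c(sc$pos, sm$pos)
    start <- max(reg$start, min(pos_all))
    end <- min(reg$end, max(pos_all))
    ml_c <- sum(sc$meth) / (sum(sc$meth) + sum(sc$unmeth))
    ml_m <- sum(sm$meth) / (sum(sm$meth) + sum(sm$unmeth))
    win_in <- wc$chrom == reg$chrom & wc$start <= reg$end &
      wc$end >= reg$start & sig
    data.frame(chrom = reg$chrom, start = start, end = end,
               length = end - start + 1L, n_sites = length(both),
               ml_control = ml_c, ml_mutant = ml_m, delta_ml = ml_m - ml_c,
               pvalue = min(p[win_in]), padj = min(padj[win_in]),
               direction = if (ml_m >= ml_c) "hyper" else "hypo",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_sites >= min_sites, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genome-wide methylation summary
#'
#' For each sample: (a) the fraction of tested cytosines called methylated,
#' per context and overall; (b) the composition of methylated cytosines
#' across CG/CHG/CHH, in percent summing to 100.
#'
#' @param calls_list named list of called site tables (from [call_sites()]),
#'   one per sample.
#' @return A list per sample with `fraction_methylated` (named vector:
#'   CG, CHG, CHH, all) and `composition_percent` (named vector summing to
#'   100; flagged all-zero when no site is methylated).
#' @export
genome_summary <- function(calls_list) {
  lapply(calls_list, function(cl) {
    tested <- !is.na(cl$methylated)
    frac <- vapply(c(CG = "CG", CHG = "CHG", CHH = "CHH"), function(cx) {
      sel <- tested & cl$context == cx
      if (!any(sel)) return(NA_real_)
      mean(cl$methylated[sel])
    }, numeric(1))
    frac <- c(frac, all = mean(cl$methylated[tested]))
    n_meth <- vapply(c(CG = "CG", CHG = "CHG", CHH = "CHH"), function(cx) {
      sum(cl$methylated[tested] & cl$context[tested] == cx)
    }, numeric(1))
    if (sum(n_meth) == 0) {
      comp <- c(CG = 0, CHG = 0, CHH = 0)
      attr(comp, "flag") <- "no methylated sites; composition undefined"
    } else comp <- 100 * n_meth / sum(n_meth)
    list(fraction_methylated = frac, composition_percent = comp)
  })
}
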