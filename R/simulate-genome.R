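#' Simulate a toy genome with gene models
#'
#' Generates random chromosome sequences, lays out non-overlapping
#' protein-coding gene models (ATG start, clean ORF, stop codon, GT..AG
#' introns, 5'/3' UTRs) with wide flanks so that upstream, downstream and
#' intergenic variant classes all occur, and appends one unmethylated
#' spike-in control sequence (record `control_unmethylated`) used to
#' estimate the bisulfite non-conversion rate.
#'
#' @param config a [sim_config()].
#' @return A list with elements `genome` (a named character vector of
#'   sequences, chromosomes plus the control record), `annotation` (a
#'   `gene_annotation` list with data frames `genes` and `features`), and
#'   `config`.
#' @examples
#' sim <- simulate_genome(sim_config(seed = 7, n_genes = 4))
#' names(sim$genome)
#' head(sim$annotation$genes)
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "genome"))
  base_probs <- c(A = 0.325, C = 0.175, G = 0.175, T = 0.325)
  chroms <- sprintf("chr%02d", seq_len(config$n_chromosomes))
  genome <- vapply(chroms, function(ch) {
    paste(sample(names(base_probs), config$chrom_length, replace = TRUE,
                 prob = base_probs), collapse = "")
  }, character(1))

  n_genes <- config$n_genes
  genes_df <- data.frame(gene_id = character(0), chrom = character(0),
                         strand = character(0), start = integer(0),
                         end = integer(0), stringsAsFactors = FALSE)
  feats_list <- list()

  if (n_genes > 0L) {
    # round-robin assignment of genes to chromosomes
    chrom_of <- chroms[((seq_len(n_genes) - 1L) %% config$n_chromosomes) + 1L]
    structures <- lapply(seq_len(n_genes), function(i) make_gene_structure())
    lens <- vapply(structures, function(s) s$length, integer(1))
    flank <- config$gene_flank
    for (ch in chroms) {
      idx <- which(chrom_of == ch)
      if (!length(idx)) next
      k <- length(idx)
      slack <- config$chrom_length - sum(lens[idx]) - (k + 1L) * flank
      if (slack < 0L)
        stop("infeasible layout: ", k, " genes (", sum(lens[idx]),
             " bp) plus ", flank, " bp flanks exceed chromosome length ",
             config$chrom_length)
      # random partition of slack into k+1 gaps
      cuts <- sort(as.integer(floor(runif(k, 0, slack + 1))))
      gaps <- diff(c(0L, cuts)) + flank
      pos <- 0L
      for (j in seq_len(k)) {
        i <- idx[j]
        gstart <- pos + gaps[j] + 1L
        gend <- gstart + lens[i] - 1L
        st <- structures[[i]]
        strand <- sample(c("+", "-"), 1L)
        gene_id <- sprintf("gene%04d", i)
        placed_seq <- if (strand == "+") st$seq else revcomp(st$seq)
        substr(genome[[ch]], gstart, gend) <- placed_seq
        genes_df <- rbind(genes_df, data.frame(
          gene_id = gene_id, chrom = ch, strand = strand,
          start = gstart, end = gend, stringsAsFactors = FALSE))
        fl <- st$features
        if (strand == "+") {
          gs <- gstart + fl$start - 1L
          ge <- gstart + fl$end - 1L
        } else {
          gs <- gstart + (st$length - fl$end)
          ge <- gstart + (st$length - fl$start)
        }
        feats_list[[length(feats_list) + 1L]] <- data.frame(
          gene_id = gene_id, type = fl$type, start = gs, end = ge,
          phase = fl$phase, stringsAsFactors = FALSE)
        pos <- gend
      }
    }
  }

  features <- if (length(feats_list)) do.call(rbind, feats_list) else
    data.frame(gene_id = character(0), type = character(0),
               start = integer(0), end = integer(0), phase = integer(0),
               stringsAsFactors = FALSE)
  features <- features[order(match(features$gene_id, genes_df$gene_id),
                             features$start), , drop = FALSE]
  rownames(features) <- NULL
  genes_df <- genes_df[order(genes_df$chrom, genes_df$start), , drop = FALSE]
  rownames(genes_df) <- NULL

  control <- paste(sample(names(base_probs), config$control_seq_length,
                          replace = TRUE, prob = base_probs), collapse = "")
  genome <- c(genome, control_unmethylated = control)

  list(genome = genome,
       annotation = structure(list(genes = genes_df, features = features),
                              class = "gene_annotation"),
       config = config)
}

# One random gene structure in transcript (sense) coordinates.
# Returns list(seq, length, features) where features has columns
# type/start/end/phase relative to the gene's 5' end on the sense strand.
make_gene_structure <- function() {
  codon_pool <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  n_ex <- sample(1:4, 1L)
  n_codons <- sample(60:240, 1L)
  codons <- c("ATG",
              sample(codon_pool, n_codons - 2L, replace = TRUE),
              sample(STOP_CODONS, 1L))
  cds <- paste(codons, collapse = "")
  L <- nchar(cds)
  if (n_ex > 1L) {
    repeat {
      cuts <- sort(sample(10:(L - 10L), n_ex - 1L))
      if (all(diff(c(0L, cuts, L)) >= 9L)) break
    }
  } else cuts <- integer(0)
  chunk_bounds <- cbind(c(1L, cuts + 1L), c(cuts, L))
  u5 <- rand_seq(sample(100:300, 1L))
  u3 <- rand_seq(sample(150:350, 1L))
  introns <- replicate(max(0L, n_ex - 1L), {
    paste0("GT", rand_seq(sample(76:396, 1L)), "AG")
  })

  # assemble sense sequence and relative coordinates
  seq_parts <- character(0)
  feats <- list()
  cursor <- 0L
  add <- function(type, len, phase = NA_integer_) {
    feats[[length(feats) + 1L]] <<- data.frame(
      type = type, start = cursor + 1L, end = cursor + len, phase = phase,
      stringsAsFactors = FALSE)
    cursor <<- cursor + len
  }
  # 5' UTR (part of exon 1)
  seq_parts <- c(seq_parts, u5)
  add("five_prime_UTR", nchar(u5))
  cds_done <- 0L
  for (e in seq_len(n_ex)) {
    chunk <- substr(cds, chunk_bounds[e, 1L], chunk_bounds[e, 2L])
    phase <- (3L - (cds_done %% 3L)) %% 3L
    seq_parts <- c(seq_parts, chunk)
    add("CDS", nchar(chunk), phase)
    cds_done <- cds_done + nchar(chunk)
    if (e < n_ex) {
      seq_parts <- c(seq_parts, introns[e])
      add("intron", nchar(introns[e]))
    }
  }
  seq_parts <- c(seq_parts, u3)
  add("three_prime_UTR", nchar(u3))
  feats <- do.call(rbind, feats)

  # exon intervals: everything that is not intron, merged between introns
  intr <- feats[feats$type == "intron", , drop = FALSE]
  total <- cursor
  ex_start <- c(1L, intr$end + 1L)
  ex_end <- c(intr$start - 1L, total)
  exons <- data.frame(type = "exon", start = ex_start, end = ex_end,
                      phase = NA_integer_, stringsAsFactors = FALSE)
  out <- rbind(exons, feats[feats$type != "intron", , drop = FALSE])
  out <- out[order(out$start, out$type), , drop = FALSE]
  list(seq = paste(seq_parts, collapse = ""), length = total, features = out)
}

rand_seq <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
}

#' Intervals of one feature type for one gene
#'
#' @param annotation a `gene_annotation` list.
#' @param gene_id gene identifier.
#' @param type feature type (`"CDS"`, `"exon"`, `"five_prime_UTR"`,
#'   `"three_prime_UTR"`).
#' @return Data frame of `start`/`end` (1-based inclusive), sorted by start.
#' @export
gene_feature_intervals <- function(annotation, gene_id, type) {
  f <- annotation$features
  out <- f[f$gene_id == gene_id & f$type == type, c("start", "end"),
           drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# Intron intervals (gaps between exons) of one gene, genomic coordinates.
gene_introns <- function(annotation, gene_id) {
  ex <- gene_feature_intervals(annotation, gene_id, "exon")
  if (nrow(ex) < 2L)
    return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1L] - 1L)
}

# Spliced CDS sequence (sense strand) of a gene; also returns a map from
# genomic position to 1-based CDS offset.
gene_cds_seq <- function(genome, annotation, gene_id) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id, ]
  stopifnot(nrow(g) == 1L)
  cds <- gene_feature_intervals(annotation, gene_id, "CDS")
  chrom_seq <- genome[[g$chrom]]
  pieces <- substring(chrom_seq, cds$start, cds$end)
  if (g$strand == "+") {
    genomic_pos <- unlist(Map(seq.int, cds$start, cds$end), use.names = FALSE)
    seq <- paste(pieces, collapse = "")
  } else {
    genomic_pos <- rev(unlist(Map(seq.int, cds$start, cds$end),
                              use.names = FALSE))
    seq <- revcomp(paste(pieces, collapse = ""))
  }
  list(seq = seq, genomic_pos = genomic_pos, strand = g$strand)
}
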