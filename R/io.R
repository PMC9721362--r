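#' Read and write FASTA
#'
#' Thin wrappers over Biostrings keeping the package's in-memory
#' representation (a named character vector of sequences).
#'
#' @param path file path.
#' @return `read_fasta`: named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param genome named character vector of sequences.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path,
                              width = 70L)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA (one per gene), exon, CDS and UTR features with
#' ID/Parent links, 1-based inclusive coordinates.
#'
#' @param annotation a `gene_annotation` list.
#' @param path output path.
#' @export
write_gff3 <- function(annotation, path) {
  genes <- annotation$genes
  feats <- annotation$features
  rows <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    mid <- paste0(g$gene_id, ".1")
    rows <- c(rows,
              paste(g$chrom, "emsomics", "gene", g$start, g$end, ".",
                    g$strand, ".", paste0("ID=", g$gene_id), sep = "\t"),
              paste(g$chrom, "emsomics", "mRNA", g$start, g$end, ".",
                    g$strand, ".",
                    paste0("ID=", mid, ";Parent=", g$gene_id), sep = "\t"))
    f <- feats[feats$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(f))) {
      ph <- if (f$type[j] == "CDS" && !is.na(f$phase[j])) f$phase[j] else "."
      rows <- c(rows, paste(g$chrom, "emsomics", f$type[j], f$start[j],
                            f$end[j], ".", g$strand, ph,
                            paste0("Parent=", mid), sep = "\t"))
    }
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports via rtracklayer and rebuilds the package's `gene_annotation`
#' structure (gene table plus exon/CDS/UTR feature table). Features are
#' attached to their gene through the mRNA Parent link.
#'
#' @param path GFF3 file.
#' @return A `gene_annotation` list.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", ]
  genes_df <- data.frame(gene_id = as.character(genes$ID),
                         chrom = as.character(genes$seqnames),
                         strand = as.character(genes$strand),
                         start = genes$start, end = genes$end,
                         stringsAsFactors = FALSE)
  mrna <- df[df$type == "mRNA", ]
  mrna_parent <- setNames(vapply(mrna$Parent, function(p)
    as.character(p)[1], character(1)), as.character(mrna$ID))
  want <- c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  fdf <- df[df$type %in% want, ]
  parent_mrna <- vapply(fdf$Parent, function(p) as.character(p)[1],
                        character(1))
  feat_gene <- unname(mrna_parent[parent_mrna])
  features <- data.frame(gene_id = feat_gene,
                         type = as.character(fdf$type),
                         start = fdf$start, end = fdf$end,
                         phase = if ("phase" %in% names(fdf))
                           as.integer(as.character(fdf$phase)) else
                             NA_integer_,
                         stringsAsFactors = FALSE)
  features <- features[order(match(features$gene_id, genes_df$gene_id),
                             features$start), , drop = FALSE]
  rownames(features) <- NULL
  genes_df <- genes_df[order(genes_df$chrom, genes_df$start), , drop = FALSE]
  rownames(genes_df) <- NULL
  structure(list(genes = genes_df, features = features),
            class = "gene_annotation")
}

#' Write variants as VCF 4.2
#'
#' Plain-text VCF with contig headers and one sample column carrying the
#' genotype (0/1 heterozygous, 1/1 homozygous).
#'
#' @param variants data frame with `chrom`, `pos`, `ref`, `alt`,
#'   `zygosity`.
#' @param chrom_lengths named vector of sequence lengths.
#' @param path output path.
#' @param sample_name sample column name.
#' @export
write_vcf <- function(variants, chrom_lengths, path,
                      sample_name = "mutant") {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=emsomics",
           sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                   as.integer(chrom_lengths)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_name, sep = "\t"))
  gt <- ifelse(variants$zygosity == "het", "0/1", "1/1")
  body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                variants$alt, ".", "PASS", ".", "GT", gt, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read variants from VCF
#'
#' Parses with vcfR, splits multi-allelic records into biallelic variants,
#' derives zygosity from the first sample's GT, and optionally validates
#' REF alleles against a genome.
#'
#' @param path VCF file.
#' @param genome optional named character vector; REF alleles are checked
#'   against it and a mismatch raises a consistency error.
#' @return Data frame: `chrom`, `pos`, `ref`, `alt`, `zygosity`, `vtype`,
#'   `size`.
#' @export
read_vcf <- function(path, genome = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF drops to vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- if (ncol(v@gt) >= 2L) vcfR::extract.gt(v, element = "GT") else NULL
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    g <- if (!is.null(gt)) gt[i, 1L] else NA_character_
    zyg <- if (is.na(g)) NA_character_
    else if (g %in% c("0/1", "0|1", "1/0", "1|0")) "het" else "hom"
    for (a in alts) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = a, zygosity = zyg,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$vtype <- mapply(variant_type, out$ref, out$alt, USE.NAMES = FALSE)
  out$size <- abs(nchar(out$alt) - nchar(out$ref))
  if (!is.null(genome)) {
    have <- substring(genome[out$chrom], out$pos,
                      out$pos + nchar(out$ref) - 1L)
    bad <- which(have != out$ref)
    if (length(bad))
      stop("consistency error between VCF and FASTA: REF mismatch at ",
           out$chrom[bad[1]], ":", out$pos[bad[1]], " (VCF ",
           out$ref[bad[1]], ", genome ", have[bad[1]], ")")
  }
  rownames(out) <- NULL
  out
}

#' Read and write the two-library count table
#'
#' TSV with columns `gene_id`, `length_bp`, `count_control`,
#' `count_mutant` (1-based conventions throughout; counts must be
#' non-negative integers).
#'
#' @param path file path.
#' @return `read_counts`: validated data frame.
#' @export
read_counts <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "length_bp", "count_control", "count_mutant")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("count table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  for (cc in c("length_bp", "count_control", "count_mutant")) {
    bad <- which(is.na(x[[cc]]) | x[[cc]] < 0)
    if (length(bad))
      stop("count table parse error at line ", bad[1] + 1L,
           ": negative or missing ", cc)
  }
  x
}

#' @rdname read_counts
#' @param counts count table data frame.
#' @export
write_counts <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write Bismark-style cytosine reports
#'
#' Tab-separated, no header: chromosome, 1-based position, strand,
#' methylated count, unmethylated count, context, trinucleotide.
#'
#' @param path file path.
#' @return `read_cytosine_report`: validated data frame with columns
#'   `chrom`, `pos`, `strand`, `meth`, `unmeth`, `context`,
#'   `trinucleotide`.
#' @export
read_cytosine_report <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("chrom", "pos", "strand", "meth", "unmeth",
                                "context", "trinucleotide"))
  bad <- which(is.na(x$meth) | is.na(x$unmeth) | x$meth < 0 | x$unmeth < 0)
  if (length(bad))
    stop("cytosine report parse error at line ", bad[1],
         ": negative or missing count")
  if (!all(x$strand %in% c("+", "-")))
    stop("cytosine report parse error: invalid strand at line ",
         which(!x$strand %in% c("+", "-"))[1])
  x
}

#' @rdname read_cytosine_report
#' @param sites cytosine table.
#' @export
write_cytosine_report <- function(sites, path) {
  write.table(sites[, c("chrom", "pos", "strand", "meth", "unmeth",
                        "context", "trinucleotide")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write intervals as BED
#'
#' BED uses 0-based half-open coordinates; the package's tables are
#' 1-based inclusive, so `start` is shifted by one on output.
#'
#' @param intervals data frame with `chrom`, `start`, `end` and optionally
#'   a `name`-like column given by `name_col`.
#' @param path output path.
#' @param name_col optional column used for the BED name field.
#' @export
write_bed <- function(intervals, path, name_col = NULL) {
  name <- if (!is.null(name_col)) intervals[[name_col]] else "."
  writeLines(paste(intervals$chrom, intervals$start - 1L, intervals$end,
                   name, sep = "\t"), path)
  invisible(path)
}
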