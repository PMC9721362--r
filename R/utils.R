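#' @importFrom stats p.adjust pbinom dbinom rbinom rpois rnbinom rgamma runif
#'   fisher.test setNames complete.cases
#' @importFrom utils read.delim write.table head
#' @importFrom methods as is
NULL

# Clamp numeric vector to [lo, hi].
clamp <- function(x, lo = 0, hi = 1) pmin(hi, pmax(lo, x))

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Reverse complement of a character vector of sequences.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(b) unname(COMPLEMENT[b])

# Three-letter amino-acid codes, "Ter" for stop.
AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              "*" = "Ter", X = "Xaa")

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Translate a nucleotide string (character) to an amino-acid string using the
# standard code; trailing incomplete codon dropped.
translate_str <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

aa_change_label <- function(ref_aa, pos, alt_aa) {
  paste0(AA_THREE[[ref_aa]], pos, AA_THREE[[alt_aa]])
}

# Stable ordering of a variants-like data frame.
order_variants <- function(df) df[order(df$chrom, df$pos, df$ref, df$alt), ,
                                  drop = FALSE]
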