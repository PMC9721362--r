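# Hand-built toy genome: one + strand gene with CDS "ATGGCTTAA" and known
# coordinates, embedded in a fixed background. Used for desk-checkable
# codon arithmetic.
toy_plus_gene <- function() {
  filler <- function(n, b = "T") strrep(b, n)
  utr5 <- "CAACAA"            # 31..36
  cds <- "ATGGCTTAA"          # 37..45
  utr3 <- "CTTCTT"            # 46..51
  seq <- paste0(filler(30, "A"), utr5, cds, utr3, filler(30, "T"))
  genome <- c(chrT = seq)
  genes <- data.frame(gene_id = "toy1", chrom = "chrT", strand = "+",
                      start = 31L, end = 51L, stringsAsFactors = FALSE)
  features <- data.frame(
    gene_id = "toy1",
    type = c("exon", "five_prime_UTR", "CDS", "three_prime_UTR"),
    start = c(31L, 31L, 37L, 46L),
    end = c(51L, 36L, 45L, 51L),
    phase = c(NA, NA, 0L, NA), stringsAsFactors = FALSE)
  list(genome = genome,
       annotation = structure(list(genes = genes, features = features),
                              class = "gene_annotation"))
}

snp <- function(chrom, pos, ref, alt) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# A moderately sized simulated dataset shared across tests (built once).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 101, n_genes = 10, chrom_length = 150000L,
                        snp_rate = 1e-3, indel_rate = 1e-4)
      sim <- simulate_genome(cfg)
      cache <<- list(cfg = cfg, sim = sim,
                     vs = simulate_variants(sim, cfg))
    }
    cache
  }
})

# Independent brute-force CpG-island oracle: literal window-by-window scan
# with explicit substring counting, merge of overlapping passing windows,
# and whole-region re-test.
cgi_oracle <- function(sequence, window = 100L, shift = 1L, min_gc = 50,
                       min_oe = 0.6, min_length = 200L) {
  n <- nchar(sequence)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (n < window) return(empty)
  chars <- strsplit(sequence, "")[[1]]
  stat <- function(a, b) {
    sub <- chars[a:b]
    nc <- sum(sub == "C"); ng <- sum(sub == "G")
    ncg <- sum(sub[-length(sub)] == "C" & sub[-1] == "G")
    len <- b - a + 1L
    ex <- nc * ng / len
    c(gc = 100 * (nc + ng) / len, oe = if (ex > 0) ncg / ex else 0)
  }
  pass_start <- integer(0)
  for (a in seq.int(1L, n - window + 1L, by = shift)) {
    s <- stat(a, a + window - 1L)
    if (s[["gc"]] >= min_gc && s[["oe"]] >= min_oe)
      pass_start <- c(pass_start, a)
  }
  if (!length(pass_start)) return(empty)
  # merge overlapping window spans
  spans <- list()
  cur <- c(pass_start[1], pass_start[1] + window - 1L)
  for (a in pass_start[-1]) {
    if (a <= cur[2] + 1L) cur[2] <- a + window - 1L
    else { spans[[length(spans) + 1L]] <- cur; cur <- c(a, a + window - 1L) }
  }
  spans[[length(spans) + 1L]] <- cur
  keep <- list()
  for (sp in spans) {
    len <- sp[2] - sp[1] + 1L
    s <- stat(sp[1], sp[2])
    if (len >= min_length && s[["gc"]] >= min_gc && s[["oe"]] >= min_oe)
      keep[[length(keep) + 1L]] <- data.frame(start = sp[1], end = sp[2])
  }
  if (!length(keep)) return(empty)
  do.call(rbind, keep)
}

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
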