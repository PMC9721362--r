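test_that("codon arithmetic matches desk examples on the toy gene", {
  toy <- toy_plus_gene()
  # CDS ATG GCT TAA; offset 6 is the T of GCT -> GCC, still Ala
  syn <- coding_effect(snp("chrT", 42, "T", "C"), "toy1", toy$genome,
                       toy$annotation, region = "exon")
  expect_equal(syn$coding_effect, "synonymous")
  expect_equal(syn$aa_change, "")
  # offset 4: GCT -> ACT, Ala2Thr
  ns <- coding_effect(snp("chrT", 40, "G", "A"), "toy1", toy$genome,
                      toy$annotation, region = "exon")
  expect_equal(ns$coding_effect, "nonsynonymous")
  expect_equal(ns$aa_change, "Ala2Thr")
  # start codon ATG -> ATA
  sl <- coding_effect(snp("chrT", 39, "G", "A"), "toy1", toy$genome,
                      toy$annotation, region = "exon")
  expect_equal(sl$coding_effect, "start_lost")
  # stop TAA -> CAA
  st <- coding_effect(snp("chrT", 43, "T", "C"), "toy1", toy$genome,
                      toy$annotation, region = "exon")
  expect_equal(st$coding_effect, "stop_lost")
  # GCT -> TAA via middle codon second base C->A? craft stop gain: GCT(40..42)
  # change 41 C->... codon GCT: G40 C41 T42; TAT?? use full check instead:
  sg <- coding_effect(snp("chrT", 40, "G", "T"), "toy1", toy$genome,
                      toy$annotation, region = "exon")
  expect_true(sg$coding_effect %in% c("nonsynonymous", "stop_gained"))
  # reference mismatch is a hard error
  expect_error(coding_effect(snp("chrT", 40, "A", "C"), "toy1", toy$genome,
                             toy$annotation, region = "exon"),
               "reference mismatch")
})

test_that("flank classification honours the strand-aware 5-kb rule", {
  toy <- toy_plus_gene()
  # widen the toy chromosome so flanks fit
  genome <- c(chrT = paste0(strrep("A", 5000), toy$genome[["chrT"]],
                            strrep("T", 7000)))
  ann <- toy$annotation
  ann$genes$start <- ann$genes$start + 5000L
  ann$genes$end <- ann$genes$end + 5000L
  ann$features$start <- ann$features$start + 5000L
  ann$features$end <- ann$features$end + 5000L
  g_end <- ann$genes$end
  down <- classify_region(snp("chrT", g_end + 3000L, "T", "A"), ann)
  expect_equal(down$region, "downstream_5kb")
  expect_equal(down$gene_id, "toy1")
  far <- classify_region(snp("chrT", g_end + 6000L, "T", "A"), ann)
  expect_equal(far$region, "intergenic")
  expect_true(is.na(far$gene_id))
  up <- classify_region(snp("chrT", ann$genes$start - 100L, "A", "G"), ann)
  expect_equal(up$region, "upstream_5kb")
  expect_error(classify_region(snp("chrZ", 5, "A", "G"), ann,
                               chroms = "chrT"),
               "unplaced")
})

test_that("splice-site variants are labelled by the intron convention", {
  base <- shared_sim()
  sim <- base$sim
  multi <- NULL
  for (gid in sim$annotation$genes$gene_id) {
    intr <- emsomics:::gene_introns(sim$annotation, gid)
    if (nrow(intr)) { multi <- list(gid = gid, intr = intr); break }
  }
  expect_false(is.null(multi))
  g <- sim$annotation$genes[sim$annotation$genes$gene_id == multi$gid, ]
  intron1 <- multi$intr[1, ]
  v_left <- snp(g$chrom, intron1$start,
                substr(sim$genome[[g$chrom]], intron1$start, intron1$start),
                "A")
  if (v_left$ref == "A") v_left$alt <- "T"
  eff <- annotate_variants(v_left, sim$genome, sim$annotation)
  expect_equal(eff$region, "splice_site")
  expect_equal(eff$coding_effect,
               if (g$strand == "+") "splice_donor" else "splice_acceptor")
  # middle of the intron is plain intron
  mid <- (intron1$start + intron1$end) %/% 2L
  v_mid <- snp(g$chrom, mid, substr(sim$genome[[g$chrom]], mid, mid), "A")
  if (v_mid$ref == "A") v_mid$alt <- "T"
  eff_mid <- annotate_variants(v_mid, sim$genome, sim$annotation)
  expect_equal(eff_mid$region, "intron")
  # the exon-anchored convention labels exon-edge bases instead
  v_edge <- snp(g$chrom, intron1$start - 1L,
                substr(sim$genome[[g$chrom]], intron1$start - 1L,
                       intron1$start - 1L), "A")
  if (v_edge$ref == "A") v_edge$alt <- "T"
  eff_exon_mode <- annotate_variants(v_edge, sim$genome, sim$annotation,
                                     splice_site_on = "exon")
  expect_equal(eff_exon_mode$region, "splice_site")
})

test_that("titv matches hand counts and is strand-complement invariant", {
  expect_equal(titv(data.frame(ref = c("A", "C", "A"),
                               alt = c("G", "T", "T"))), 2.0)
  expect_equal(titv(data.frame(ref = "A", alt = "C")), 0.0)
  base <- shared_sim()
  v <- base$vs$variants
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  v2 <- v[v$vtype == "snp", ]
  v2$ref <- unname(comp[v2$ref]); v2$alt <- unname(comp[v2$alt])
  expect_equal(titv(v2), titv(v[v$vtype == "snp", ]))
})

test_that("variant summaries count, partition and histogram correctly", {
  vars <- data.frame(
    chrom = "c1", pos = c(10, 20, 30, 40),
    ref = c("A", "A", "A", "ATT"),
    alt = c("AT", "AG", "AC", "A"),
    zygosity = c("hom", "hom", "hom", "hom"), stringsAsFactors = FALSE)
  effects <- data.frame(chrom = "c1", pos = vars$pos, ref = vars$ref,
                        alt = vars$alt, gene_id = NA_character_,
                        region = "intergenic", coding_effect = "none",
                        aa_change = "", stringsAsFactors = FALSE)
  s <- variant_summaries(vars, effects)
  expect_equal(s$het_fraction, 0)
  hist <- s$indel_histogram
  expect_equal(hist$count[hist$size == 1], 3L)
  expect_equal(hist$count[hist$size == -2], 1L)
  expect_equal(sum(s$region_percent), 100, tolerance = 1e-9)

  base <- shared_sim()
  eff <- annotate_variants(base$vs$variants, base$sim$genome,
                           base$sim$annotation)
  s2 <- variant_summaries(base$vs$variants, eff)
  expect_equal(sum(s2$region_percent), 100, tolerance = 1e-9)
  expect_equal(sum(s2$per_chromosome$n_variants), nrow(base$vs$variants))
})

test_that("mutated gene set applies class filter with set semantics", {
  eff <- data.frame(
    chrom = "c1", pos = 1:5, ref = "A", alt = "G",
    gene_id = c("g1", "g1", "g1", "g2", "g3"),
    region = "exon",
    coding_effect = c("nonsynonymous", "nonsynonymous", "nonsynonymous",
                      "synonymous", "frameshift"),
    aa_change = "", stringsAsFactors = FALSE)
  expect_equal(mutated_gene_set(eff), c("g1", "g3"))
  expect_equal(mutated_gene_set(eff, classes = "nonsynonymous"), "g1")
  # a gene with nonsynonymous SNP and frameshift indel appears once
  eff2 <- rbind(eff, data.frame(chrom = "c1", pos = 6, ref = "AT",
                                alt = "A", gene_id = "g1", region = "exon",
                                coding_effect = "frameshift",
                                aa_change = "", stringsAsFactors = FALSE))
  expect_equal(sum(mutated_gene_set(eff2) == "g1"), 1L)
})

test_that("fast annotator equals the brute-force oracle on random variants", {
  base <- shared_sim()
  v <- base$vs$variants[, c("chrom", "pos", "ref", "alt")]
  fast <- annotate_variants(v, base$sim$genome, base$sim$annotation)
  ref <- annotate_variants_reference(v, base$sim$genome,
                                     base$sim$annotation)
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  m <- match(key(ref), key(fast))
  expect_false(anyNA(m))
  expect_identical(ref$region, fast$region[m])
  expect_identical(ref$coding_effect, fast$coding_effect[m])
  expect_identical(ref$aa_change, fast$aa_change[m])
})
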