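test_that("gene region spans promoter to 3'UTR, strand-aware, clipped", {
  gp <- data.frame(chrom = "c", strand = "+", start = 10001L, end = 13000L)
  expect_equal(gene_region(gp, 20000L), list(start = 8001L, end = 13000L))
  gm <- data.frame(chrom = "c", strand = "-", start = 10001L, end = 13000L)
  expect_equal(gene_region(gm, 20000L), list(start = 10001L, end = 15000L))
  ge <- data.frame(chrom = "c", strand = "+", start = 500L, end = 2000L)
  expect_equal(gene_region(ge, 20000L), list(start = 1L, end = 2000L))
  gz <- data.frame(chrom = "c", strand = "-", start = 19500L, end = 19900L)
  expect_equal(gene_region(gz, 20000L), list(start = 19500L, end = 20000L))
})

test_that("island scan matches closed-form extremes", {
  isl <- find_cgis(strrep("CG", 150))
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$start, 1L)
  expect_equal(isl$end, 300L)
  expect_equal(isl$gc_percent, 100)
  expect_equal(isl$obs_exp_cpg, 2.0)
  expect_equal(nrow(find_cgis(strrep("A", 300))), 0L)
  expect_equal(nrow(find_cgis("ACGT")), 0L)  # shorter than one window
})

test_that("island scan equals the exhaustive window oracle", {
  set.seed(37)
  for (i in 1:20) {
    gc <- runif(1, 0.3, 0.65)
    seq <- rand_dna(1000, gc = gc)
    got <- find_cgis(seq)
    want <- cgi_oracle(seq)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      # every reported island satisfies all three thresholds as a region
      expect_true(all(got$length >= 200))
      expect_true(all(got$gc_percent >= 50))
      expect_true(all(got$obs_exp_cpg >= 0.6))
    }
  }
})

test_that("methylated sites are counted per context inside islands", {
  calls <- list(
    control = data.frame(chrom = "c", pos = c(10L, 50L, 70L, 400L),
                         context = c("CG", "CG", "CHH", "CG"),
                         methylated = c(TRUE, TRUE, TRUE, TRUE)),
    mutant = data.frame(chrom = "c", pos = c(10L, 50L, 70L),
                        context = c("CG", "CG", "CHH"),
                        methylated = c(FALSE, FALSE, FALSE)))
  island <- data.frame(chrom = "c", start = 1L, end = 300L)
  cnt <- count_meth_in_cgi(island, calls)
  expect_equal(unname(cnt["control", ]), c(2, 0, 1))
  expect_equal(unname(cnt["mutant", ]), c(0, 0, 0))
  empty <- count_meth_in_cgi(data.frame(chrom = "c", start = 1000L,
                                        end = 1100L), calls)
  expect_true(all(empty == 0))
})

test_that("pattern classification encodes anti-correlation", {
  up <- data.frame(gene_id = "g", status = "up", log2fc = 2)
  down <- data.frame(gene_id = "g", status = "down", log2fc = -2)
  expect_equal(classify_pattern(up, -3)$pattern, "opposite")
  expect_equal(classify_pattern(down, -3)$pattern, "concordant")
  expect_equal(classify_pattern(up, 0)$pattern, "flat")
  expect_equal(classify_pattern(down, 3)$pattern, "opposite")
  ns <- data.frame(gene_id = "g", status = "ns", log2fc = 0.1)
  expect_error(classify_pattern(ns, 1), "not applicable")
})

test_that("per-gene islands map back to chromosome coordinates", {
  # gene with a strong island planted in its promoter
  isl_seq <- strrep("CG", 150)
  left <- rand_dna(3000, gc = 0.3)
  right <- rand_dna(3000, gc = 0.3)
  genome <- c(chrC = paste0(left, isl_seq, right))
  genes <- data.frame(gene_id = "gX", chrom = "chrC", strand = "+",
                      start = 3500L, end = 5200L, stringsAsFactors = FALSE)
  ann <- structure(list(genes = genes,
                        features = data.frame(gene_id = character(0),
                                              type = character(0),
                                              start = integer(0),
                                              end = integer(0),
                                              phase = integer(0))),
                   class = "gene_annotation")
  isl <- find_gene_cgis(ann, genome)
  expect_gte(nrow(isl), 1L)
  expect_true(any(isl$start <= 3001 + 10 & isl$end >= 3300 - 10))
  expect_equal(isl$gene_id[1], "gX")
})
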