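test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(seed = 13, n_genes = 4, chrom_length = 100000L)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$annotation, b$annotation)
  fa <- tempfile(fileext = ".fasta"); fb <- tempfile(fileext = ".fasta")
  write_fasta(a$genome, fa); write_fasta(b$genome, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
  va <- simulate_variants(a, cfg); vb <- simulate_variants(b, cfg)
  expect_identical(va$variants, vb$variants)
  ma <- simulate_methylome(a, cfg); mb <- simulate_methylome(b, cfg)
  expect_identical(ma$sites_mutant, mb$sites_mutant)
})

test_that("degenerate and infeasible layouts are handled", {
  s0 <- simulate_genome(sim_config(seed = 3, n_genes = 0))
  expect_equal(nrow(s0$annotation$genes), 0L)
  expect_true("control_unmethylated" %in% names(s0$genome))
  expect_error(
    simulate_genome(sim_config(seed = 1, n_genes = 50,
                               chrom_length = 20000L, n_chromosomes = 1)),
    "infeasible")
})

test_that("every generated CDS translates cleanly with the standard code", {
  cfg <- sim_config(seed = 21, n_genes = 50, chrom_length = 500000L,
                    n_chromosomes = 2)
  sim <- simulate_genome(cfg)
  for (gid in sim$annotation$genes$gene_id) {
    cds <- emsomics:::gene_cds_seq(sim$genome, sim$annotation, gid)
    expect_equal(nchar(cds$seq) %% 3L, 0L)
    prot <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds$seq)))
    expect_equal(substr(prot, 1, 1), "M")
    expect_equal(substr(prot, nchar(prot), nchar(prot)), "*")
    expect_false(grepl("*", substr(prot, 1, nchar(prot) - 1), fixed = TRUE))
  }
})

test_that("SNP spectrum follows the configured transition fraction", {
  base <- shared_sim()
  cfg1 <- sim_config(seed = 31, n_genes = 4, chrom_length = 100000L,
                     snp_rate = 2e-3, transition_fraction = 1)
  sim1 <- simulate_genome(cfg1)
  v1 <- simulate_variants(sim1, cfg1)$variants
  s1 <- v1[v1$vtype == "snp", ]
  pair <- paste0(s1$ref, s1$alt)
  expect_true(all(pair %in% c("AG", "GA", "CT", "TC")))
  expect_identical(titv(v1), Inf)

  # het fraction within 3 binomial SDs of the configured 0.946
  cfg2 <- sim_config(seed = 32, n_genes = 4, n_chromosomes = 4,
                     chrom_length = 400000L, snp_rate = 4.5e-3)
  sim2 <- simulate_genome(cfg2)
  v2 <- simulate_variants(sim2, cfg2)$variants
  n <- nrow(v2)
  expect_gt(n, 5000)
  se <- sqrt(0.946 * 0.054 / n)
  expect_lt(abs(mean(v2$zygosity == "het") - 0.946), 3 * se)

  # Ti/Tv close to f/(1-f) = 1.43 at the default transition fraction
  expect_lt(abs(titv(v2) - 0.589 / 0.411), 0.15)
  expect_true(all(v2$size[v2$vtype != "snp"] < 50))
})

test_that("count generator plants the stated effects", {
  cfg0 <- sim_config(seed = 41, n_genes = 2000, n_de_genes = 0,
                     mean_count = 50)
  cts0 <- simulate_counts(2000L, cfg0)
  lfc <- log2fc(cts0$counts$count_control, cts0$counts$count_mutant)
  expect_lt(abs(mean(lfc)), 0.05)

  # planted two-fold-squared effect: expected 4:1 mutant/control ratio
  cfg1 <- sim_config(seed = 42, n_genes = 400, n_de_genes = 100,
                     de_log2fc = 2, mean_count = 200, nb_dispersion = 0.01)
  cts1 <- simulate_counts(400L, cfg1)
  up <- cts1$truth$gene_id[cts1$truth$direction == "up"]
  i <- match(up, cts1$counts$gene_id)
  ratio <- sum(cts1$counts$count_mutant[i]) /
    sum(cts1$counts$count_control[i])
  expect_lt(abs(ratio - 4), 0.5)

  # dispersion -> 0 limit stays within Poisson range of the mean
  cfg2 <- sim_config(seed = 43, n_genes = 500, n_de_genes = 0,
                     nb_dispersion = 0, mean_count = 100)
  cts2 <- simulate_counts(500L, cfg2)
  v <- var(cts2$counts$count_control)
  m <- mean(cts2$counts$count_control)
  # gamma-distributed means dominate; variance must not exceed NB blow-up
  expect_lt(v, 2 * (m + m^2 / 2))
  expect_error(simulate_counts(100L, sim_config(seed = 1, n_genes = 100,
                                                n_de_genes = 10,
                                                de_log2fc = 0)),
               "invalid truth")
})

test_that("methylome generator reproduces its truth parameters", {
  base <- shared_sim()
  cfg <- base$cfg
  meth <- simulate_methylome(base$sim, cfg)

  # unmethylated control reads appear methylated at the non-conversion rate
  ctrl <- meth$sites_control[meth$sites_control$chrom ==
                               "control_unmethylated", ]
  tot <- sum(ctrl$meth) + sum(ctrl$unmeth)
  r_hat <- sum(ctrl$meth) / tot
  se <- sqrt(cfg$nonconversion_rate * (1 - cfg$nonconversion_rate) / tot)
  expect_lt(abs(r_hat - cfg$nonconversion_rate), 3 * se)

  # planted DMRs realize the configured mean ML difference
  for (i in seq_len(nrow(meth$truth))) {
    d <- meth$truth[i, ]
    sel_c <- meth$sites_control$chrom == d$chrom &
      meth$sites_control$pos >= d$start & meth$sites_control$pos <= d$end
    sel_m <- meth$sites_mutant$chrom == d$chrom &
      meth$sites_mutant$pos >= d$start & meth$sites_mutant$pos <= d$end
    ml_c <- with(meth$sites_control[sel_c, ], sum(meth) /
                   sum(meth + unmeth))
    ml_m <- with(meth$sites_mutant[sel_m, ], sum(meth) / sum(meth + unmeth))
    expect_lt(abs((ml_m - ml_c) - d$delta), 0.05)
  }
  # truth DMR intervals do not overlap
  tr <- meth$truth[order(meth$truth$chrom, meth$truth$start), ]
  same <- tr$chrom[-1] == tr$chrom[-nrow(tr)]
  expect_true(all(tr$start[-1][same] > tr$end[-nrow(tr)][same]))

  # noiseless null: no methylation levels, no non-conversion, no signal
  cfg0 <- sim_config(seed = 77, n_genes = 2, chrom_length = 50000L,
                     n_chromosomes = 1, meth_level_cg = 0,
                     meth_level_chg = 0, meth_level_chh = 0,
                     nonconversion_rate = 0, n_dmrs = 0)
  sim0 <- simulate_genome(cfg0)
  m0 <- simulate_methylome(sim0, cfg0)
  expect_true(all(m0$sites_control$meth == 0))
  expect_true(all(m0$sites_mutant$meth == 0))
})

test_that("re-annotating generated variants reproduces the truth labels", {
  base <- shared_sim()
  eff <- annotate_variants(base$vs$variants, base$sim$genome,
                           base$sim$annotation)
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  m <- match(key(base$vs$truth), key(eff))
  expect_false(anyNA(m))
  expect_identical(base$vs$truth$region, eff$region[m])
  expect_identical(base$vs$truth$coding_effect, eff$coding_effect[m])
  expect_identical(base$vs$truth$aa_change, eff$aa_change[m])
})
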