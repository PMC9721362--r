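test_that("context calls match the trinucleotide definitions", {
  expect_equal(context_of(c(x = "ACGT"), "x", 2, "+"), "CG")
  expect_equal(context_of(c(x = "ACAGT"), "x", 2, "+"), "CHG")
  expect_equal(context_of(c(x = "ACAAT"), "x", 2, "+"), "CHH")
  # minus strand reads through the reverse complement
  expect_equal(context_of(c(x = "ACGT"), "x", 3, "-"), "CG")
  expect_equal(context_of(c(x = "CCTGA"), "x", 4, "-"), "CHG")
  expect_error(context_of(c(x = "ACGT"), "x", 1, "+"), "not a cytosine")
})

test_that("vectorized cytosine enumeration equals a per-position scan", {
  set.seed(19)
  seq <- rand_dna(400, gc = 0.45)
  genome <- c(chrX = seq)
  sites <- cytosine_sites(genome)
  # oracle: naive character-by-character walk of both strands
  chars <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  expected <- list()
  for (p in seq_along(chars)) {
    if (chars[p] == "C") {
      b1 <- if (p + 1 <= length(chars)) chars[p + 1] else "N"
      b2 <- if (p + 2 <= length(chars)) chars[p + 2] else "N"
      ctx <- if (b1 == "G") "CG" else if (b2 == "G") "CHG" else "CHH"
      expected[[length(expected) + 1]] <- c(p, "+", ctx)
    }
    if (chars[p] == "G") {
      b1 <- if (p - 1 >= 1) comp[[chars[p - 1]]] else "N"
      b2 <- if (p - 2 >= 1) comp[[chars[p - 2]]] else "N"
      ctx <- if (b1 == "G") "CG" else if (b2 == "G") "CHG" else "CHH"
      expected[[length(expected) + 1]] <- c(p, "-", ctx)
    }
  }
  exp_df <- do.call(rbind, expected)
  key_got <- paste(sites$pos, sites$strand, sites$context)
  key_exp <- paste(exp_df[, 1], exp_df[, 2], exp_df[, 3])
  expect_setequal(key_got, key_exp)
  expect_equal(nrow(sites), nrow(exp_df))
})

test_that("non-conversion estimation is the pooled read fraction", {
  ctl <- data.frame(meth = c(1, 3), unmeth = c(5000, 4996))
  est <- estimate_nonconversion(ctl)
  expect_equal(est$rate, 0.0004)
  expect_equal(est$n_reads_used, 10000)
  expect_equal(estimate_nonconversion(
    data.frame(meth = 0, unmeth = 100))$rate, 0)
  expect_error(estimate_nonconversion(data.frame(meth = 0, unmeth = 0)),
               "zero coverage")
  expect_error(estimate_nonconversion(
    data.frame(meth = 100, unmeth = 900)), "implausible")
  set.seed(23)
  depth <- rpois(5000, 20)
  meth <- rbinom(5000, depth, 3e-4)
  est2 <- estimate_nonconversion(data.frame(meth = meth,
                                            unmeth = depth - meth))
  se <- sqrt(3e-4 * (1 - 3e-4) / sum(depth))
  expect_lt(abs(est2$rate - 3e-4), 3 * se)
})

test_that("ML correction follows the closed form and its properties", {
  expect_equal(correct_ml(0.0004, 0.0004), 0)
  expect_equal(correct_ml(1, 0.3), 1)
  expect_equal(correct_ml(0.25, 0.0004), (0.25 - 0.0004) / (1 - 0.0004))
  expect_equal(round(correct_ml(0.25, 0.0004), 4), 0.2497)
  expect_equal(correct_ml(0.37, 0), 0.37)
  expect_error(correct_ml(0.5, 1), "invalid")
  # monotone increasing in ml, decreasing in r
  ml <- seq(0, 1, by = 0.05)
  expect_true(all(diff(correct_ml(ml, 0.01)) > 0))
  expect_true(all(correct_ml(0.5, c(0, 0.01, 0.02)) ==
                    cummin(correct_ml(0.5, c(0, 0.01, 0.02)))))
})

test_that("site p-values equal exact binomial tail sums", {
  grid <- expand.grid(cov = c(1L, 5L, 10L, 20L, 50L),
                      r = c(1e-4, 0.004, 0.01, 0.05))
  for (i in seq_len(nrow(grid))) {
    cov <- grid$cov[i]; r <- grid$r[i]
    sites <- data.frame(meth = 0:cov, unmeth = cov:0)
    out <- call_sites(sites, r, min_coverage = 1L)
    manual <- vapply(0:cov, function(m)
      sum(choose(cov, m:cov) * r^(m:cov) * (1 - r)^(cov - (m:cov))),
      numeric(1))
    expect_equal(out$pvalue, manual, tolerance = 1e-12)
  }
  # spot value from the definition
  p5 <- call_sites(data.frame(meth = 5, unmeth = 5), 0.01,
                   min_coverage = 1L)$pvalue
  expect_lt(abs(p5 - sum(dbinom(5:10, 10, 0.01))), 1e-12)
  # zero methylated reads carry no evidence
  expect_equal(call_sites(data.frame(meth = 0, unmeth = 10),
                          0.01)$pvalue, 1)
})

test_that("null site p-values are valid (ECDF dominated by uniform)", {
  set.seed(29)
  n <- 20000
  depth <- rpois(n, 20)
  r <- 0.004
  meth <- rbinom(n, depth, r)
  out <- call_sites(data.frame(meth = meth, unmeth = depth - meth), r,
                    min_coverage = 1L)
  p <- out$pvalue
  grid <- seq(0.01, 1, by = 0.01)
  ecdf_p <- vapply(grid, function(g) mean(p <= g), numeric(1))
  # valid p-values: P(p <= g) <= g (+ Monte-Carlo slack)
  expect_true(all(ecdf_p <= grid + 3 * sqrt(grid * (1 - grid) / n) + 1e-6))
})

test_that("window grid follows the start/width/step rule", {
  # chromosome of 4200 bp: starts 1, 601, 1201; last window ends at 4200
  sites <- data.frame(chrom = "c", pos = c(1L, 700L, 1300L, 4200L),
                      meth = c(3L, 1L, 0L, 2L), unmeth = c(1L, 0L, 4L, 0L),
                      context = "CG", stringsAsFactors = FALSE)
  w <- make_windows(sites, c(c = 4200L))
  expect_setequal(unique(w$start), c(1L, 601L, 1201L))
  expect_equal(max(w$end), 4200L)
  # single-site window ml
  one <- data.frame(chrom = "c", pos = 50L, meth = 3L, unmeth = 1L,
                    context = "CHH", stringsAsFactors = FALSE)
  w1 <- make_windows(one, c(c = 4200L))
  expect_equal(w1$ml[w1$start == 1L], 0.75)
  # each covered site is in at most window/step windows
  set.seed(31)
  many <- data.frame(chrom = "c", pos = sample(1:4200, 300),
                     meth = 1L, unmeth = 1L, context = "CG",
                     stringsAsFactors = FALSE)
  wm <- make_windows(many, c(c = 4200L))
  expect_gte(sum(wm$n_sites), 300)
  expect_lte(sum(wm$n_sites), 5 * 300)
})

test_that("DMR calling handles null, extreme and swapped inputs", {
  base <- shared_sim()
  cfg <- base$cfg
  meth <- simulate_methylome(base$sim, cfg)
  gc_ <- meth$sites_control[meth$sites_control$chrom != "control_unmethylated", ]
  gm_ <- meth$sites_mutant[meth$sites_mutant$chrom != "control_unmethylated", ]
  lens <- vapply(base$sim$genome, nchar, integer(1))
  lens <- lens[setdiff(names(lens), "control_unmethylated")]
  wc <- make_windows(gc_, lens)
  wm <- make_windows(gm_, lens)
  # identical samples: no DMRs
  none <- call_dmrs(wc, wc, gc_, gc_)
  expect_equal(nrow(none), 0L)
  # planted DMRs are recovered with the right direction
  dmrs <- call_dmrs(wc, wm, gc_, gm_)
  expect_gte(nrow(dmrs), 1L)
  for (i in seq_len(nrow(meth$truth))) {
    tr <- meth$truth[i, ]
    hit <- dmrs$chrom == tr$chrom & dmrs$start <= tr$end &
      dmrs$end >= tr$start
    expect_true(any(hit))
    expect_true(tr$direction %in% dmrs$direction[hit])
  }
  # antisymmetry: swapping samples flips direction, keeps intervals
  rev <- call_dmrs(wm, wc, gm_, gc_)
  expect_equal(dmrs[, c("chrom", "start", "end")],
               rev[, c("chrom", "start", "end")])
  expect_equal(dmrs$delta_ml, -rev$delta_ml, tolerance = 1e-12)
  expect_true(all(dmrs$direction != rev$direction))
  # every DMR respects the site floor and has positive length
  expect_true(all(dmrs$n_sites >= 3L))
  expect_true(all(dmrs$end >= dmrs$start))
  # grids built with different geometry are rejected
  wc2 <- make_windows(gc_, lens, window = 2000L, step = 500L)
  expect_error(call_dmrs(wc2, wm, gc_, gm_), "grid mismatch")
})

test_that("an extreme 2x2 window yields a hypo DMR with delta -1", {
  sites_c <- data.frame(chrom = "c", pos = seq(100L, 1000L, by = 10L),
                        strand = "+", meth = 2L, unmeth = 0L,
                        context = "CG", stringsAsFactors = FALSE)
  sites_m <- sites_c
  sites_m$meth <- 0L; sites_m$unmeth <- 2L
  lens <- c(c = 3000L)
  wc <- make_windows(sites_c, lens)
  wm <- make_windows(sites_m, lens)
  d <- call_dmrs(wc, wm, sites_c, sites_m)
  expect_equal(nrow(d), 1L)
  expect_equal(d$delta_ml, -1)
  expect_equal(d$direction, "hypo")
  expect_lt(d$padj, 1e-10)
  # trimmed to the outermost covered cytosines
  expect_equal(d$start, 100L)
  expect_equal(d$end, 1000L)
})

test_that("per-context methylated fractions recover the truth parameters", {
  # depth 50: site calling has ~full power at ML 0.8 and singleton reads
  # fall above the BH cutoff, isolating generator-caller recovery
  cfg <- sim_config(seed = 909, n_chromosomes = 1, chrom_length = 200000L,
                    n_genes = 4, n_dmrs = 0, read_depth = 50)
  sim <- simulate_genome(cfg)
  meth <- simulate_methylome(sim, cfg)
  ctrl <- meth$sites_control[meth$sites_control$chrom ==
                               "control_unmethylated", ]
  nc <- estimate_nonconversion(ctrl)
  genomic <- meth$sites_control[meth$sites_control$chrom !=
                                  "control_unmethylated", ]
  calls <- call_sites(genomic, nc$rate)
  gs <- genome_summary(list(s = calls))$s
  truth <- c(CG = cfg$meth_level_cg, CHG = cfg$meth_level_chg,
             CHH = cfg$meth_level_chh)
  for (cx in names(truth)) {
    n_cx <- sum(!is.na(calls$methylated) & calls$context == cx)
    se <- sqrt(truth[[cx]] * (1 - truth[[cx]]) / n_cx)
    expect_lt(abs(gs$fraction_methylated[[cx]] - truth[[cx]]),
              3 * se + 0.002)
  }
})

test_that("genome summary normalizes composition and flags empties", {
  calls <- data.frame(context = c("CG", "CG", "CHG", "CHH"),
                      methylated = c(TRUE, FALSE, TRUE, FALSE))
  gs <- genome_summary(list(s = calls))$s
  expect_equal(sum(gs$composition_percent), 100, tolerance = 1e-9)
  expect_equal(unname(gs$fraction_methylated["CG"]), 0.5)
  empty <- data.frame(context = "CG", methylated = FALSE)
  gs0 <- genome_summary(list(s = empty))$s
  expect_equal(as.numeric(gs0$composition_percent), c(0, 0, 0))
  expect_match(attr(gs0$composition_percent, "flag"), "undefined")
})
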