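#' Simulate EMS-style variants with truth labels
#'
#' Draws SNPs and small indels over the simulated chromosomes (never the
#' spike-in control). SNPs are transitions with probability
#' `transition_fraction` and heterozygous with probability `het_fraction`;
#' indel sizes follow a truncated geometric below `max_indel` (< 50 bp),
#' insertions and deletions equally likely. Indels whose affected span
#' would straddle a feature boundary are redrawn so every variant has one
#' well-defined region label. Every variant receives a truth effect label
#' computed with the full-translation reference annotator
#' ([annotate_variants_reference()]).
#'
#' @param sim result of [simulate_genome()].
#' @param config a [sim_config()] (defaults to the one inside `sim`).
#' @param planted_genes optional gene ids that must each receive one
#'   nonsynonymous CDS SNP (used to plant multi-omics candidate genes).
#' @return List with `variants` (data frame: `chrom`, `pos`, `ref`, `alt`,
#'   `zygosity`, `vtype`, `size`) and `truth` (the reference effect table,
#'   one row per variant).
#' @export
simulate_variants <- function(sim, config = sim$config,
                              planted_genes = NULL) {
  set.seed(stage_seed(config$seed, "variants"))
  chroms <- setdiff(names(sim$genome), "control_unmethylated")
  lens <- vapply(chroms, function(ch) nchar(sim$genome[[ch]]), integer(1))
  total <- sum(lens)

  n_snp <- rbinom(1L, total, config$snp_rate)
  n_indel <- rbinom(1L, total, config$indel_rate)

  draw_positions <- function(n) {
    flat <- sample.int(total - 120L, n) + 60L
    cum <- cumsum(lens)
    ci <- findInterval(flat - 1L, c(0L, cum[-length(cum)]))
    data.frame(chrom = chroms[ci],
               pos = flat - c(0L, cum)[ci],
               stringsAsFactors = FALSE)
  }

  snp_df <- NULL
  if (n_snp > 0L) {
    ps <- draw_positions(n_snp)
    ref <- substring(sim$genome[ps$chrom], ps$pos, ps$pos)
    is_ti <- runif(n_snp) < config$transition_fraction
    ti_partner <- c(A = "G", G = "A", C = "T", T = "C")
    tv_partners <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
    alt <- character(n_snp)
    alt[is_ti] <- ti_partner[ref[is_ti]]
    if (any(!is_ti))
      alt[!is_ti] <- vapply(ref[!is_ti],
                            function(b) sample(tv_partners[[b]], 1L),
                            character(1))
    snp_df <- data.frame(chrom = ps$chrom, pos = ps$pos, ref = ref,
                         alt = alt, vtype = "snp", size = 0L,
                         stringsAsFactors = FALSE)
  }

  indel_df <- NULL
  if (n_indel > 0L) {
    region_label <- region_labeler(sim$annotation)
    made <- list()
    attempts <- 0L
    while (length(made) < n_indel && attempts < 20L * n_indel + 50L) {
      attempts <- attempts + 1L
      p <- draw_positions(1L)
      size <- 1L + stats::rgeom(1L, 0.4)
      if (size > config$max_indel) next
      L <- lens[[p$chrom]]
      is_ins <- runif(1L) < 0.5
      span_end <- if (is_ins) p$pos + 1L else p$pos + size + 1L
      if (span_end > L - 2L) next
      labs <- region_label(p$chrom, p$pos:span_end)
      if (length(unique(labs)) != 1L) next
      anchor_base <- substr(sim$genome[[p$chrom]], p$pos, p$pos)
      if (is_ins) {
        ref <- anchor_base
        alt <- paste0(anchor_base, rand_seq(size))
      } else {
        ref <- substr(sim$genome[[p$chrom]], p$pos, p$pos + size)
        alt <- anchor_base
      }
      made[[length(made) + 1L]] <- data.frame(
        chrom = p$chrom, pos = p$pos, ref = ref, alt = alt,
        vtype = if (is_ins) "insertion" else "deletion", size = size,
        stringsAsFactors = FALSE)
    }
    if (length(made)) indel_df <- do.call(rbind, made)
  }

  variants <- rbind(snp_df, indel_df)
  planted_df <- NULL
  if (!is.null(planted_genes)) {
    planted_df <- do.call(rbind, lapply(planted_genes, function(gid) {
      plant_nonsynonymous(sim, gid)
    }))
    variants <- rbind(variants, planted_df)
  }
  if (is.null(variants) || !nrow(variants)) {
    variants <- data.frame(chrom = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           vtype = character(0), size = integer(0),
                           stringsAsFactors = FALSE)
  }
  variants <- order_variants(variants)
  # enforce spacing so no two edits interact (keeps truth unambiguous)
  keep <- rep(TRUE, nrow(variants))
  if (nrow(variants) > 1L) {
    planted_key <- if (!is.null(planted_df))
      paste(planted_df$chrom, planted_df$pos) else character(0)
    last_pos <- -Inf; last_chrom <- ""
    for (i in seq_len(nrow(variants))) {
      if (variants$chrom[i] == last_chrom &&
          variants$pos[i] - last_pos < 60L &&
          !(paste(variants$chrom[i], variants$pos[i]) %in% planted_key)) {
        keep[i] <- FALSE
      } else {
        last_pos <- variants$pos[i]; last_chrom <- variants$chrom[i]
      }
    }
  }
  variants <- variants[keep, , drop = FALSE]
  if (any(variants$pos < 1L |
          variants$pos + nchar(variants$ref) - 1L >
          lens[variants$chrom]))
    stop("variant generation error: position outside sequence bounds")
  variants$zygosity <- ifelse(runif(nrow(variants)) < config$het_fraction,
                              "het", "hom")
  rownames(variants) <- NULL

  truth <- annotate_variants_reference(
    variants[, c("chrom", "pos", "ref", "alt")], sim$genome,
    sim$annotation)
  # one row per variant: genes never overlap in the simulated layout
  truth <- truth[!duplicated(paste(truth$chrom, truth$pos, truth$ref,
                                   truth$alt)), , drop = FALSE]
  list(variants = variants, truth = truth)
}

# Fast single-position region labeler used to reject boundary-crossing
# indels during generation.
region_labeler <- function(annotation) {
  genes <- annotation$genes
  feats <- annotation$features
  function(chrom, positions) {
    vapply(positions, function(p) {
      g <- genes[genes$chrom == chrom & genes$start <= p & genes$end >= p, ]
      if (!nrow(g)) return("outside")
      gid <- g$gene_id[1L]
      f <- feats[feats$gene_id == gid & feats$type != "exon" &
                   feats$start <= p & feats$end >= p, ]
      if (nrow(f)) paste(gid, f$type[1L]) else paste(gid, "intron")
    }, character(1))
  }
}

# Place one guaranteed-nonsynonymous SNP in the CDS of a gene.
plant_nonsynonymous <- function(sim, gene_id) {
  cs <- gene_cds_seq(sim$genome, sim$annotation, gene_id)
  n_codons <- nchar(cs$seq) %/% 3L
  for (ci in sample(2:(n_codons - 1L))) {
    codon <- substr(cs$seq, 3L * ci - 2L, 3L * ci)
    for (within in 1:3) {
      ref_sense <- substr(codon, within, within)
      for (alt_sense in setdiff(c("A", "C", "G", "T"), ref_sense)) {
        alt_codon <- codon
        substr(alt_codon, within, within) <- alt_sense
        aa_r <- Biostrings::GENETIC_CODE[[codon]]
        aa_a <- Biostrings::GENETIC_CODE[[alt_codon]]
        if (aa_r != aa_a && aa_a != "*") {
          o <- 3L * (ci - 1L) + within
          gpos <- cs$genomic_pos[o]
          g <- sim$annotation$genes[
            sim$annotation$genes$gene_id == gene_id, ]
          if (cs$strand == "+") {
            ref <- ref_sense; alt <- alt_sense
          } else {
            ref <- comp_base(ref_sense); alt <- comp_base(alt_sense)
          }
          return(data.frame(chrom = g$chrom, pos = gpos, ref = ref,
                            alt = alt, vtype = "snp", size = 0L,
                            stringsAsFactors = FALSE))
        }
      }
    }
  }
  stop("could not plant a nonsynonymous SNP in ", gene_id)
}

#' Simulate a two-library count table
#'
#' Draws per-gene negative-binomial counts for one control and one mutant
#' library. Gene means are gamma-distributed around `mean_count`; planted
#' DE genes have the mutant mean shifted by `de_log2fc` (alternating up and
#' down); all genes share means otherwise, scaled by `lib_size_ratio` in
#' the mutant library.
#'
#' @param genes a `gene_annotation` (gene lengths from summed exon widths),
#'   or an integer number of genes (lengths then drawn 500-4000 bp).
#' @param config a [sim_config()].
#' @return List with `counts` (data frame: `gene_id`, `length_bp`,
#'   `count_control`, `count_mutant`) and `truth` (data frame: `gene_id`,
#'   `direction` for planted DE genes).
#' @export
simulate_counts <- function(genes, config) {
  set.seed(stage_seed(config$seed, "counts"))
  if (inherits(genes, "gene_annotation")) {
    ids <- genes$genes$gene_id
    length_bp <- vapply(ids, function(gid) {
      ex <- gene_feature_intervals(genes, gid, "exon")
      sum(ex$end - ex$start + 1L)
    }, integer(1))
  } else {
    n <- as.integer(genes)
    ids <- sprintf("gene%04d", seq_len(n))
    length_bp <- sample(500:4000, n, replace = TRUE)
  }
  n <- length(ids)
  n_de <- min(config$n_de_genes, n)
  if (n_de > 0L && config$de_log2fc == 0)
    stop("invalid truth: n_de_genes > 0 with de_log2fc = 0")
  mu <- rgamma(n, shape = 2, scale = config$mean_count / 2)
  de_idx <- if (n_de > 0L) sort(sample.int(n, n_de)) else integer(0)
  direction <- rep(c("up", "down"), length.out = n_de)
  fc <- rep(1, n)
  fc[de_idx] <- 2^(ifelse(direction == "up", 1, -1) * config$de_log2fc)
  mu_mut <- mu * fc * config$lib_size_ratio
  draw <- function(m) {
    if (config$nb_dispersion < 1e-8) rpois(n, m)
    else rnbinom(n, mu = m, size = 1 / config$nb_dispersion)
  }
  counts <- data.frame(gene_id = ids, length_bp = as.integer(length_bp),
                       count_control = draw(mu),
                       count_mutant = draw(mu_mut),
                       stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = ids[de_idx], direction = direction,
                      stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
}

#' Simulate two bisulfite cytosine reports with planted DMRs
#'
#' Enumerates every cytosine of the genome on both strands, assigns each a
#' true methylation level (`methylated_ml` with the per-context probability,
#' 0 otherwise; the spike-in control is fully unmethylated), plants
#' `n_dmrs` non-overlapping regions of `dmr_length` bp where the two
#' samples' levels are set symmetrically around 0.5 so that the mean
#' methylation-level difference across the region is exactly `dmr_delta`
#' (signed; hyper and hypo alternate), and draws Poisson read depths with
#' binomially distributed methylated counts at probability
#' `ml + (1 - ml) * r`, where `r` is the non-conversion rate. A `dmr_delta`
#' that would push a level outside `[0, 1]` is clipped with a warning.
#'
#' @param sim result of [simulate_genome()].
#' @param config a [sim_config()].
#' @param dmr_in_genes optional gene ids; one planted DMR is centred on
#'   each (counted against `n_dmrs`).
#' @return List with `sites_control` and `sites_mutant` (cytosine tables:
#'   `chrom`, `pos`, `strand`, `meth`, `unmeth`, `context`,
#'   `trinucleotide`) and `truth` (data frame of planted DMRs: `chrom`,
#'   `start`, `end`, `delta`, `direction`).
#' @export
simulate_methylome <- function(sim, config = sim$config,
                               dmr_in_genes = NULL) {
  set.seed(stage_seed(config$seed, "methylome"))
  sites <- cytosine_sites(sim$genome)
  on_control <- sites$chrom == "control_unmethylated"
  level <- c(CG = config$meth_level_cg, CHG = config$meth_level_chg,
             CHH = config$meth_level_chh)[sites$context]
  state <- runif(nrow(sites)) < level & !on_control
  ml1 <- ifelse(state, config$methylated_ml, 0)

  chroms <- setdiff(names(sim$genome), "control_unmethylated")
  lens <- vapply(chroms, function(ch) nchar(sim$genome[[ch]]), integer(1))
  dmrs <- plant_dmr_intervals(sim, config, chroms, lens, dmr_in_genes)

  ml2 <- ml1
  if (nrow(dmrs)) {
    clipped <- FALSE
    for (i in seq_len(nrow(dmrs))) {
      sel <- sites$chrom == dmrs$chrom[i] & sites$pos >= dmrs$start[i] &
        sites$pos <= dmrs$end[i]
      lo <- 0.5 - dmrs$delta[i] / 2
      hi <- 0.5 + dmrs$delta[i] / 2
      if (lo < 0 || lo > 1 || hi < 0 || hi > 1) clipped <- TRUE
      ml1[sel] <- clamp(lo, 0, 1)
      ml2[sel] <- clamp(hi, 0, 1)
    }
    if (clipped)
      warning("dmr_delta pushed site probabilities outside [0, 1]; ",
              "values were clipped")
  }

  r <- config$nonconversion_rate
  draw_sample <- function(ml) {
    depth <- rpois(nrow(sites), config$read_depth)
    pm <- ml + (1 - ml) * r
    meth <- rbinom(nrow(sites), depth, pm)
    data.frame(chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
               meth = meth, unmeth = depth - meth, context = sites$context,
               trinucleotide = sites$trinucleotide, stringsAsFactors = FALSE)
  }
  list(sites_control = draw_sample(ml1), sites_mutant = draw_sample(ml2),
       truth = dmrs)
}

plant_dmr_intervals <- function(sim, config, chroms, lens, dmr_in_genes) {
  n <- config$n_dmrs
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), delta = numeric(0),
                    direction = character(0), stringsAsFactors = FALSE)
  if (n <= 0L) return(out)
  len_dmr <- config$dmr_length
  made <- list()
  if (!is.null(dmr_in_genes)) {
    for (gid in dmr_in_genes) {
      g <- sim$annotation$genes[sim$annotation$genes$gene_id == gid, ]
      centre <- (g$start + g$end) %/% 2L
      start <- max(1L, centre - len_dmr %/% 2L)
      made[[length(made) + 1L]] <- data.frame(
        chrom = g$chrom, start = start,
        end = min(lens[[g$chrom]], start + len_dmr - 1L),
        stringsAsFactors = FALSE)
    }
  }
  guard <- 0L
  while (length(made) < n && guard < 50L * n + 100L) {
    guard <- guard + 1L
    ch <- sample(chroms, 1L, prob = lens / sum(lens))
    if (lens[[ch]] <= len_dmr + 2L) next
    start <- sample.int(lens[[ch]] - len_dmr, 1L)
    end <- start + len_dmr - 1L
    # keep planted regions > 2 windows apart so calls stay identifiable
    ok <- TRUE
    for (m in made)
      if (m$chrom == ch && m$start <= end + 8000L &&
          m$end >= start - 8000L) ok <- FALSE
    if (ok) made[[length(made) + 1L]] <- data.frame(
      chrom = ch, start = start, end = end, stringsAsFactors = FALSE)
  }
  dmrs <- do.call(rbind, made)
  dmrs$delta <- rep(c(-1, 1), length.out = nrow(dmrs)) * config$dmr_delta
  dmrs$direction <- ifelse(dmrs$delta > 0, "hyper", "hypo")
  dmrs[order(dmrs$chrom, dmrs$start), , drop = FALSE]
}
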