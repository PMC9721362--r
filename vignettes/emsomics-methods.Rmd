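---
title: "Methods and design of the emsomics pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the emsomics pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emsomics)
```

`emsomics` dissects an EMS-mutagenized line against its progenitor on three
omics layers — DNA variants, expression, DNA methylation — and integrates
them into candidate genes. This vignette explains the statistical models,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
the problem was genuinely open.

## 1. Variant-effect annotation

Variants (SNPs and indels < 50 bp, VCF left-anchored) are classified
against gene models with priority CDS > splice site > UTR > intron >
gene flank > intergenic; flanks extend 5,000 bp from the gene span,
strand-aware (`upstream_5kb` / `downstream_5kb`), and a flank variant goes
to the nearest gene (exact ties to the lexicographically smaller gene id).
Indels are anchored at their first affected base; the generator never
emits an indel whose affected span straddles a feature boundary, so truth
labels are unambiguous.

Coding consequences of CDS SNPs are computed at the codon level
(synonymous, nonsynonymous, `stop_gained`, `stop_lost`, `start_lost`),
with amino-acid changes in three-letter notation (`Ser107Gly`). CDS indels
are `frameshift` when their size is not a multiple of three, otherwise
`codon_insertion`/`codon_deletion`. A 5'UTR SNP that creates a new ATG on
the sense strand in a window overlapping the mutated base is
`start_gained` — the narrowest testable reading of a "transcription start
gained" class. The package carries a second, deliberately brute-force
annotator (`annotate_variants_reference()`) that classifies regions by
exhaustive interval scans and SNP consequences by rebuilding and
translating the entire mutant protein; the generator uses it for truth
labels and the tests hold the fast annotator to 100% agreement with it.

**Splice-site convention.** The conventional definition — the first/last
2 bp of an *intron* (donor GT, acceptor AG) — is the default, matching the
class names `splice_donor`/`splice_acceptor`. A literal "first or last
2 bp of an *exon*" reading is available via
`splice_site_on = "exon"`; in that mode the exon-edge windows take
priority over the CDS class, since they would otherwise never be labelled.

## 2. No-replicate differential expression

With one library per condition there is no within-group dispersion to
estimate, so the test models technical/sampling noise only: conditioned on
a gene's total count \(k = k_c + k_m\), the mutant count is
\(k_m \mid k \sim \mathrm{Bin}(k,\; N_m/(N_c+N_m))\) under the null of
equal relative expression, where \(N_c, N_m\) are effective library
totals. The two-sided p-value is `min(1, 2·min(lower tail, upper tail))`,
computed exactly at every total via the regularized incomplete beta
(`pbinom`); a separate large-count approximation would buy nothing and was
deliberately not added. Genes with zero counts in both libraries are
removed before testing (and before the BH `m` is fixed); `k = 0` gives
p = 1 by convention.

Library scaling uses the single TMM factor (trimmed mean of M-values, 30%
trim on log-ratios, 5% on intensity; control as reference), computed by
edgeR behind `scaling_factor()`. The factor is split symmetrically across
the two effective totals (\(N_c/\sqrt f\), \(N_m\sqrt f\), a product-one
normalization), so that swapping the two libraries negates every log2
fold change and leaves every p-value unchanged — an invariance the test
suite checks exactly.

Fold changes are computed on normalized expression (FPKM,
\(10^9 \cdot \mathrm{count} / (\mathrm{length} \cdot N)\)) as
\(\log_2((m+p)/(c+p))\) with pseudocount \(p = 0.1\) applied **only when
either value is zero**. DEGs require BH-adjusted p < 0.005 and fold change
≥ 2 (|log2FC| ≥ 1); `up`/`down`/`ns` partition the tested genes.

*Limitation:* the conditional binomial test is anticonservative when true
biological replicates exist, because it ignores between-replicate
dispersion. It is the appropriate model only for the one-library-per-
condition design it serves here, and the generator's default NB dispersion
(0.01) is accordingly technical-replicate-scale; at biological-scale
dispersion (0.1–0.5) the realized FDR of any no-replicate test degrades.

## 3. Methylome

**Contexts.** Each cytosine's context is read from the two bases
downstream on its own strand: CG, CHG (H = A/C/T), else CHH; cytosines
within 2 bp of a sequence end whose context cannot be determined fall back
to CHH and are flagged.

**Non-conversion and correction.** The bisulfite non-conversion rate *r*
is the pooled methylated-read fraction over an unmethylated spike-in
control sequence (the standard mechanism for obtaining such a rate; the
generator writes it as the FASTA record `control_unmethylated`). Rates
≥ 0.05 are rejected as implausible. Methylation levels are corrected as
\((ML - r)/(1 - r)\), clamped to \([0,1]\) — the identity at r = 0,
monotone in both arguments.

**Site calls.** A site with coverage ≥ 5 (the conventional 5× threshold;
configurable) is called methylated when the exact binomial upper-tail
probability of its methylated count at rate *r* survives BH at FDR 0.05.
A single *r* per sample is used for all contexts, as the correction
formula implies.

**Windows and DMRs.** Counts are summed in 3,000-bp windows sliding by
600 bp. The grid starts at 1, 601, 1201, … and stops with the first
window that reaches the chromosome end, which is truncated there; windows
never span chromosomes, and windows with no covered cytosine are omitted.
The window ML is the count-sum ratio (summed methylated over summed
total), not the mean of per-site MLs, following the "sum of methylated and
unmethylated read counts" aggregation. How windows become DMRs was an open
design point; the package uses: per-window two-sided Fisher exact test on
the two samples' (methylated, unmethylated) sums, BH across windows,
significance at FDR 0.05 with |ΔML| ≥ 0.1 and ≥ 3 covered cytosines,
merging of overlapping/abutting significant windows, and trimming of each
merged region to its outermost covered cytosine. The trim is what lets
reported DMRs be far shorter than one window (tens of bp). DMR calling is
antisymmetric by construction: swapping samples flips every direction and
keeps every interval.

CG sites are not strand-collapsed; no merge rule is imposed on symmetric
CpGs.

## 4. CpG islands and methylation–expression patterns

For each DEG, the sequence from 2,000 bp upstream of the transcription
start to the 3'UTR end (gene end when un-annotated, clipped to the
chromosome) is scanned with the classic Gardiner-Garden & Frommer
procedure: 100-bp windows sliding 1 bp; windows with GC ≥ 50% and
ObsCpG/ExpCpG ≥ 0.6 (Exp = C·G/len; Obs counts CG dinucleotides fully
inside the window) are merged; merged regions are reported when ≥ 200 bp
and the thresholds hold for the region as a whole. All five parameters are
configurable. Ns count toward length but not toward C or G.

Within each island, methylated-called sites are counted per context and
per sample; a gene's methylation difference is the summed mutant-minus-
control methylated-site count across its islands (a ΔML-based alternative
is a one-line change via `count_meth_in_cgi`). A DEG is `opposite` when
expression and CGI methylation move in opposite directions, `flat` at zero
difference, else `concordant`.

## 5. Integration

Set R contains genes with at least one large-impact variant
(nonsynonymous, stop/start gain or loss, splice acceptor/donor, codon
insertion/deletion, frameshift); a nonsynonymous-only preset is available
since published Venn diagrams sometimes use that narrower set. Set T is
the called DEGs; set M is the genes whose body or promoter (2,000 bp,
matching the CGI convention) overlaps a DMR by ≥ 1 bp — promoter-inclusive
overlap was chosen because promoter methylation is the mechanistically
expected route from a DMR to an expression change. All seven Venn cells
are computed exactly and reconstruct the input set sizes; candidates in
≥ 2 layers are tabulated with expression values and explicit NA markers
for genes never quantified.

## 6. The synthetic-data generator

One master seed drives everything; each stage derives an independent
substream keyed by its name (`stage_seed()`), so adding a stage never
perturbs earlier outputs, and identical configurations give byte-identical
files.

What it emulates, with the emulation targets as defaults:

* *Genome and genes* — random 35%-GC chromosomes; non-overlapping gene
  models with ATG start, internally stop-free ORF, GT..AG introns, UTRs,
  and ≥ 12-kb flanks so all region classes occur.
* *Variants* — transition fraction 0.589 (giving Ti/Tv = 0.589/0.411 ≈
  1.43), heterozygous fraction 0.946, geometric indel sizes < 50 bp,
  truth effect labels from the full-translation reference annotator.
* *Counts* — gamma-distributed gene means around 50, NB dispersion 0.01
  (technical scale, matching the single-library design), 10% planted DE
  genes at |log2FC| = 2 alternating up/down, a library-size ratio
  parameter defaulting to 1 (no depth difference is imposed).
* *Methylome* — per-context methylation probabilities 0.576 / 0.328 /
  0.026 (CG/CHG/CHH); a methylated cytosine has true ML 0.8; Poisson read
  depth (default 20, the whole-genome scale of a ~16× study design);
  non-conversion noise at 4 × 10⁻⁴ genome-wide and on the spike-in
  control. Planted DMRs set the two samples' levels symmetrically around
  0.5 (e.g. 0.3 vs 0.7 for Δ = 0.4), so the realized mean ML difference
  across the region equals the configured Δ exactly rather than being
  eroded by clipping; planted regions are kept > 2 window-widths apart so
  their calls stay identifiable.

What it does **not** emulate: read-level data (no FASTQ, no alignment or
M-bias artifacts), sequencing error beyond non-conversion, paralogy and
repeat structure of a real plant genome, biological replicate dispersion,
and context-specific ML distributions. Passing tests therefore demonstrate
the correctness and calibration of the statistics under their own model
assumptions, not robustness to every artifact of real libraries.

## 7. Problem sizes and numerical choices

The test suite exercises parameter recovery at the scales a desk
validation supports: DE recovery on 5,000 genes with 500 planted effects;
DMR recovery with 20 planted 4-kb regions on a 2-Mb two-chromosome
genome at depth 20; oracle equivalences on ≥ 1,000 random variants and
100 random 5-kb sequences; a 50,000-site null methylome for FDR behaviour.
Context-level methylation recovery is evaluated at depth 50: at that
coverage the binomial site call has essentially full power at true
ML 0.8 while singleton methylated reads (upper-tail p ≈ 0.02) fall above
the BH cutoff, so the recovered per-context fractions isolate the
generator–caller round trip from boundary false calls; at depth 20 a
singleton's p-value (≈ 0.008) sits near the adaptive BH threshold and
contributes a small, expected false-call share to the sparse CHH class.

Other numerical conventions: BH via `p.adjust` (step-up with enforced
monotonicity, order-preserving); Fisher tests via `fisher.test` on the
2×2 read-sum tables; binomial tails via `pbinom` (exact at all counts);
coordinates 1-based inclusive everywhere except BED output (0-based
half-open, converted on write); multi-allelic VCF records split into
biallelic variants before annotation; a variant overlapping two genes
yields one record per gene (the simulated layout never overlaps genes).

## 8. Known limitations

* The no-replicate DE test quantifies sampling noise only (Section 2).
* DMR boundaries inherit window resolution outward: a merged region can
  extend up to one window beyond the true differential segment before
  trimming, so boundary accuracy is coarser than detection accuracy.
* `start_gained` uses the narrowest local-ATG definition; promoter or
  Kozak context is not modelled.
* Unanchored scaffolds and genes on them are out of scope; inputs are
  assumed to live on assembled chromosomes plus the spike-in control.
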