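---
title: "Calling polyadenylation sites and mapping apaQTL: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling polyadenylation sites and mapping apaQTL: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyacall)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It covers the read-level filters, the site and
usage model, the 3′-Seq peak caller, the benchmarking metrics, the apaQTL
scan, and — since every guarantee the test suite makes is a statement about
simulated data — what the synthetic-data generator does and does not
emulate.

## 1. From soft clips to cleavage events

A long read that captures a cleavage/polyadenylation event ends in a
non-templated polyA tail. After alignment the tail survives as the soft
clip at the transcript-3′ end of the read: the trailing clip for `+`
strand alignments, the leading clip reverse-complemented for `-` strand
alignments. `parse_alignments()` normalizes both to a 5′→3′
transcript-oriented string, and records the cleavage position as the first
reference base past the aligned 3′ end.

**Tail call** (`classify_polya_tail()`). A clip is a polyA tail when

* it is shorter than 20 nt, at least 6 nt long, and ≥ 95 % adenosine; or
* it is ≥ 20 nt long, its first 20 nt are ≥ 80 % adenosine, and the
  following segment (nt 21–40, or the remainder when the clip is shorter
  than 40 nt) is ≥ 95 % adenosine.

Both thresholds are inclusive. The second rule's "following segment" is
applied to remainders shorter than 20 nt at the same 95 % threshold; a
20-nt clip has an empty remainder and is judged on its first rule alone.
This has a visible consequence: a 21–39-nt tail with a single non-A base
in its remainder fails (1/19 > 5 %), so at a 2 % per-base tail impurity
about a sixth of such tails are discarded. That is faithful rule
behaviour, not a bug, and it is why the simulation default is 80 reads per
gene (section 6). A `consecutive = TRUE` switch additionally requires a
run of six adenosines, for users who prefer the run-based reading of the
minimum-stretch rule; the count-based composition rules are the default
because they are the operational definition of the filtering procedure.

**Mispriming filter** (`filter_mispriming()`). Oligo-dT primers can anneal
to genomically templated A-stretches, producing reads that end at a
spurious "cleavage site". The filter scans the genomic flanks of the
cleavage position on the transcript strand (T's on the reference for `-`
strand events). Two modes reflect the two protocols:

* `longread`: misprimed when the 10-nt upstream **or** 10-nt downstream
  flank contains ≥ 6 adenosines (a count rule);
* `3seq`: misprimed when the combined 22-nt window (10 up, 12 down)
  contains a **run** of ≥ 6 consecutive adenosines.

Both flanks exclude the cleavage base itself; "upstream" is the
transcript-5′ side. Under this convention the 3′-Seq window is the
concatenation of the two flanks around the skipped cleavage base; the run
test is applied to that concatenation. The two modes are both exposed on
every entry point because the two protocols phrase the rule differently,
and the distinction matters: six scattered A's fire the count rule but not
the run rule.

## 2. PAS sites and usage

A PAS site is the 100-nt window ending at the cleavage coordinate:
`[position − 100, position)` on `+`, `[position, position + 100)` on `-`.
One deliberate asymmetry follows from the coordinate definitions (the
cleavage position is itself the first *unaligned* base): recovery
comparisons therefore treat windows as closed intervals
(`site_recovery()`), which makes the check symmetric across strands.

How per-read windows become discrete sites is a genuinely open design
point; `build_pas_windows()` merges overlapping same-strand windows and
pools their read counts (the default), or clusters cleavage positions
within 24 nt (`merge = "cluster"`). Merging is the default because it is
parameter-free and exactly reproduces the window definition when cleavage
positions are ≥ 100 nt apart.

Sites are assigned to the same-strand gene overlapping their window; ties
prefer a gene whose annotated 3′ UTR contains the cleavage position, then
the nearest annotated transcript end. Context is labelled
3UTR/5UTR/exon/intron from the gene model; 3′ UTR sites are kept only if
at least one supporting read has an aligned block overlapping exonic
sequence upstream of that UTR — this removes internal-priming and
degradation artifacts that produce reads wholly contained in the UTR.

`quantify_pau()` computes `pau = read_count / gene_read_total` **before**
any filtering, drops genes with fewer than `min_gene_reads = 40` polyA
reads (inclusive ≥, so 39 fails), then drops sites with `pau ≤ min_pau`
(strict >, so exactly 5 % fails) *without* rescaling the survivors — the
reported usages remain fractions of the full gene. `rescale_pau()` exists
for the separate situation where unannotatable sites are removed and the
per-gene composition should be restored to sum to one. The ≥ 40-read
total counts all events assigned to the gene, not only events at
surviving sites.

## 3. 3′-Seq peak calling

3′-Seq concentrates read ends at PAS, so sites appear as peaks in per-base
end-coverage. `ricker_convolve()` convolves the coverage with the second
derivative of a Gaussian,

$$ g''(k) = \left(\frac{k^2}{\sigma^4} - \frac{1}{\sigma^2}\right)
            e^{-k^2 / 2\sigma^2}, $$

truncated at ± 4σ and zero-padded at the edges. The kernel is negative at
the origin, so coverage peaks become minima of the convolved signal.
`call_peaks()` takes as centers the local minima that are negative and
have read ends within the kernel half-width — the neighbourhood
requirement, rather than a per-base one, because end counts are sparse
and the true minimum regularly falls on a base with zero raw count inside
a genuine pile. Each center claims the read ends within ± 4σ (nearest
center wins); peaks with `mean_support = support / n_libraries` strictly
below `min_mean_reads = 5` are discarded, so a peak at exactly the
threshold is kept ("fewer than" is strict). Windows extend 100 nt
transcript-upstream of the center, putting 3′-Seq peaks in exactly the
same coordinate convention as long-read sites, so both flow through the
same gene assignment and usage quantification.

σ defaults to 15 nt. The bandwidth of the original convolution-based
caller is not published, so σ is an exposed tuning parameter validated by
planted-peak recovery: at σ = 15 the caller recovers > 95 % of planted
peaks of bandwidth 10 nt with center error ≤ σ, resolves peaks ≥ 6σ
apart, and calls false peaks on Poisson-background loci at well under 5 %.

## 4. Motif and flank QC

Genuine cleavage sites carry a signal-site hexamer (canonically AATAAA)
~20–30 nt upstream and a GU/GT-rich element ~10–30 nt downstream.
`positional_motif_profile()` counts motif starts at every offset in the
± 100-nt transcript-oriented flank (every distinct start offset counts
once). `motif_enrichment_test()` compares motif presence in the upstream
`[−30, −20]` offset window against a control window — by default the
downstream mirror `[+20, +30]`, a choice the package makes explicit since
no canonical background construction exists; odds ratios are
cross-product ratios with a Haldane 0.5 correction for empty cells, and
p-values are one-sided Fisher exact tests. `downstream_gt_content()`
dichotomizes per-site G+T fraction in `[+10, +30]` at 0.6 ("GT-rich" has
no standard definition; 0.6 is well above the 0.5 expectation of a
uniform background) against random control offsets in ± [60, 100].

One statistical caveat is worth stating plainly: Fisher exact p-values on
sparse 2×2 tables are discrete and conservative. On null data (no planted
signal) their distribution is stochastically *larger* than uniform — the
test never over-rejects, but a KS test against uniformity will reject the
conservative direction. The test suite therefore asserts the absence of
anti-conservatism (the fraction of p ≤ 0.05 stays at or below nominal)
rather than exact uniformity.

## 5. Benchmarking metrics

`match_sites()` matches two site sets one-to-one, greedily by decreasing
same-strand overlap with ties broken toward the 5′-most partner.
One-to-one matching (rather than the many-to-many of a plain interval
intersection) is what makes per-site usage comparisons well defined.

`pau_error()` is the per-gene `Sum|ΔPAU|`: matched pairs contribute
`|pau_a − pau_b|`, and unmatched sites contribute their full usage, so two
methods calling disjoint site sets score the maximum of 2. Whether
unmatched mass should count is debatable — both behaviours are exposed
(`matched_only`) — but including it is the default because it realizes
the intended meaning of maximal discordance for completely different
calls.

`roc_auc()` sweeps the test method's usage threshold while holding the
truth definition fixed (reference sites with PAU > 5 %): TPR(t) is the
fraction of truth sites matched by a test site with PAU > t, FPR(t) the
fraction of unmatched test sites above max(t, 5 %) among all unmatched
test sites above 5 %. The sweep variable is the package's choice (the
operating-point definitions fix only one point); AUC is the trapezoid
area with (0,0) and (1,1) endpoints, and equals brute-force threshold
enumeration exactly on instances up to 50 sites.

`proximal_distal_shift()` restricts to genes with ≥ 2 3′ UTR sites whose
proximal (5′-most) and distal (3′-most) cleavage positions are ≥ 500 bp
apart and counts genes whose distal usage is higher in one table than the
other. `two_proportion_test()` is the pooled two-proportion χ² with 1 df
and no continuity correction; degenerate pooled proportions return
χ² = 0, p = 1.

## 6. The apaQTL stack

Usage phenotypes are bounded, skewed compositions, so each site is
standardized and inverse-normal transformed: values are replaced by
`qnorm((rank − 0.5)/n)` with averaged ranks for ties. Standardizing first
is order-preserving and hence redundant for the transform; it is retained
to mirror the conventional two-step recipe. Four sample-space principal
components are then regressed out of every site and residuals
re-standardized (`remove_confounders()`; `n_pcs = 0` is the identity). One
caution, verified in simulation: with only a handful of phenotypes, the
top PCs align with the strongest per-site signals — including genuine genotype effects — so PC correction on very
small site sets removes signal, not confounding. It is meant for matrices
with hundreds of sites, where shared technical structure dominates.

`cis_scan()` regresses transformed usage on dosage (mean-imputed per
variant) for every variant with MAF ≥ 0.05 within ± 25 kb of the site
(± 1 Mb reproduces the eQTL-style scan). `lead_permutation_fdr()` takes
each site's smallest nominal p and compares it against the distribution
of per-site minimum p-values over `n_perm = 1000` permutations of sample
labels: `perm_p = (1 + #{min p_perm ≤ p_obs}) / (n_perm + 1)`. Direct
permutation replaces the beta-approximated permutation p of FastQTL-style
scans: exact at this scale, with no distributional assumption, at the
cost of a p-value floor of `1/(n_perm+1)`. Significance is
Benjamini–Hochberg on the permutation p-values at FDR 10 % (Storey
q-values are available via `fdr_method = "storey"`; which FDR procedure
the convention implies is ambiguous, so both are implemented with BH as
the default).

`pi1_sharing()` estimates the shared fraction of associations as
`π1 = 1 − π0`, with `π0(λ) = #{p > λ} / ((1 − λ) m)` on the grid
λ = 0.05…0.90, smoothed by a cubic smoothing spline (df = 3) and read at
the largest λ; below 100 pairs it falls back to the fixed λ = 0.5
estimator, and below 20 pairs it warns. Two properties of this estimator
matter when reading results: it inherits sampling noise of order
`1/sqrt(m(1−λ))` (sd ≈ 0.05–0.08 at m = 1000), and for alternatives with
density at p = 1 (e.g. Beta(0.1, 1), which leaves density 0.1 there) even
the oracle estimator is biased low by that density times the alternative
fraction. The test suite therefore checks mixture recovery on replicate
averages.

## 7. What the simulator emulates — and what it does not

`sim_config(seed)` fixes the study conditions; all defaults were chosen
once, as follows:

* **50 genes, 1–5 PAS each, spaced 200 nt in the 3′ UTR**; usage from a
  symmetric Dirichlet(α = 5), i.e. moderately balanced compositions where
  minor sites still clear the 5 % usage cut at realistic depth.
* **80 reads per gene**, of which 10 % are internally primed at planted
  A₁₃ decoys (in the half of genes carrying one) and 5 % are tail-less.
  80 is the depth at which every gene stays above the 40-polyA-read
  coverage filter after the ~15 % loss that the strict tail-purity rule
  inflicts at 2 % per-base tail impurity.
* **Tails** of mean length 30 nt (5 + Poisson), 2 % per-base non-A error.
* **Signal structure**: every planted PAS gets AATAAA at offset −25 and a
  GT element at +15; its mispriming flanks are drawn A-poor; accidental
  A/T homopolymer runs ≥ 6 anywhere in the genome are broken during
  generation, so the decoy rate is exactly the configured one.
* **3′-Seq**: end positions Normal(PAS, σ = 10) discretized; per-library
  counts Poisson(30 · PAU) across 6 libraries; uniform Poisson background
  at 0.02/base. Libraries draw from derived sub-seeds, so tracks differ
  between libraries but are reproducible.
* **Cohorts**: 60 samples; dosages Binomial(2, f), f ~ U(0.1, 0.5);
  planted variants shift the distal-site usage linearly in dosage on the
  logit scale to a target latent R² = 0.2, with logit-normal residual
  noise; per-gene usages renormalize to 1.

Determinism is hierarchical: the master seed derives per-stage child
seeds, so changing one stage's draw count does not reshuffle the others,
and identical configurations are byte-identical across runs.

Equally important is what the generator does **not** model, and hence
what green tests do not certify about real data: cleavage-position
heterogeneity around a site (real cleavage scatters over ~10–20 nt;
planted long-read cleavage is exact, which is what makes per-site PAU
exactly binomial), homopolymer-specific sequencing error, reads from
degraded or incompletely processed transcripts, overlapping genes,
linkage disequilibrium between variants (they are simulated independent,
which makes the permutation-test multiplicity *harsher* than in real LD
blocks), and population or batch structure beyond a rank-1 effect.

## 8. Numerical and testing choices

Problem sizes in the routine test suite were chosen so the whole suite
exercises every claim on a desk machine: a 12-gene fixture for module
tests, the full 50-gene default for the end-to-end checks, 100-replicate
power and null batches for the QTL stack, and exhaustive enumeration
where the space is small (all {A,C} clips to length 12; all A/C flank
windows; all 2×2 tables with margins ≤ 30 against a hypergeometric
oracle). Two documented limits surface there: the detection power of the
permutation-FDR pipeline at latent R² = 0.2, MAF 0.3, n = 60 with ~10
independent cis variants is ≈ 0.85–0.88 (the nominal p must beat the ~1 %
quantile of a 10-variant min-p null; at R² = 0.5 power is ≈ 1), and
Fisher-exact null p-values are conservative rather than uniform
(section 4). Both are properties of the methods under the stated
conditions, not tunable defects, and the corresponding assertions in the
acceptance tests record them honestly.
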