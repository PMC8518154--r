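# polyacall

Identification and quantification of alternative polyadenylation from
long-read and 3′-end sequencing, with cross-method benchmarking and cis
apaQTL mapping.

## The problem

Most human genes carry several cleavage/polyadenylation sites (PAS), so one
gene produces mRNA isoforms with different 3′ ends. Which site is used —
the **polyadenylation site usage (PAU)**, the fraction of a gene's
polyA-supported reads ending at each site — varies across tissues and
individuals and is under genetic control. `polyacall` implements the full
analysis stack for this problem:

* **Long-read (Iso-Seq-style) PAS calling.** Reads that capture a cleavage
  event end in a non-templated polyA tail that aligners report as a 3′ soft
  clip. A soft clip is accepted as a tail when it is shorter than 20 nt
  with ≥ 95 % adenosine (and at least a six-adenosine stretch), or ≥ 20 nt
  with ≥ 80 % A in its first 20 nt and ≥ 95 % A in the following segment.
  Reads whose genomic flanks look like oligo-dT mispriming substrates —
  ≥ 6 A in the 10 nt upstream or the 10 nt downstream of the cleavage
  site — are discarded. Each surviving read yields a cleavage event; PAS
  sites are the 100-nt windows ending at the cleavage coordinate
  (overlapping windows merged), assigned to genes and genic context from a
  GTF, with 3′ UTR sites additionally required to have a supporting read
  spanning an upstream exon. PAU is
  `reads ending at the site / reads ending at any site of the gene`,
  computed over genes with ≥ 40 polyA reads; sites with PAU > 5 % form the
  high-confidence set.
* **3′-Seq peak calling.** Read-end coverage is convolved with the second
  derivative of a Gaussian, `g''(k) = (k²/σ⁴ − 1/σ²)·exp(−k²/2σ²)`;
  negative local minima of the convolved signal are peak centers, extended
  100 nt upstream, and peaks supported by fewer than an average of 5 reads
  per library are discarded. A 22-nt flank window (10 up / 12 down) with a
  run of ≥ 6 adenosines marks misprimed ends.
* **Sequence-level QC.** Positional profiles of the signal-site hexamers
  (AATAAA, ATTAAA, AGTAAA, TATAAA, CATAAA, GATAAA; AAAAAA as negative
  control) around called cleavage sites, one-sided Fisher enrichment of
  the upstream [−30, −20] window, and downstream GT-content checks.
* **Benchmarking.** One-to-one site matching by interval overlap, the
  per-gene discordance `Error(Sum|ΔPAU|) ∈ [0, 2]`, ROC/AUC with truth
  sites defined at PAU > 5 %, proximal/distal 3′ UTR shift fractions, and
  a pooled two-proportion χ² test.
* **apaQTL mapping.** Per-site standardization + inverse-normal quantile
  normalization of a samples × sites PAU matrix, removal of 4 principal
  components, simple-regression cis scans (± 25 kb, MAF ≥ 0.05; ± 1 Mb for
  the eQTL variant of the scan), direct permutation of sample labels for
  the lead-association p-value, Benjamini–Hochberg FDR < 10 %, and
  Storey's π1 for sharing between result sets.
* **Synthetic data.** A seeded generator that plants everything the
  pipeline is supposed to find — PAS positions and usage compositions,
  polyA tails with configurable impurity, genomic A-stretch decoys,
  Gaussian 3′-Seq peaks, genotype-linked usage shifts — so every module is
  validated against known truth.

All coordinates are 0-based half-open throughout; PAS BED files are BED6+1
(name = `gene:site`, score = read count, column 7 = PAU).

## Worked example

```r
library(polyacall)

cfg    <- sim_config(seed = 1)                  # 50 genes, 1-5 PAS each
ref    <- simulate_reference(cfg)
reads  <- simulate_long_reads(cfg, ref)
sam    <- file.path(tempdir(), "reads.sam")
write_sam(reads, ref$genome, sam)

events <- extract_cleavage_events(parse_alignments(sam), ref$genome,
                                  mode = "longread")
sites  <- assign_and_filter(build_pas_windows(events), events,
                            ref$gene_models)
pau    <- quantify_pau(sites, min_gene_reads = 40, min_pau = 0.05)
pau
#> pau_table: 148 PAS sites in 50 genes
#>    chrom start  end strand gene_id read_count       pau context
#> 1   chrS   850  950      + gene001         46 1.0000000    3UTR
#> 72  chrS  1849 1949      - gene002         54 1.0000000    3UTR
#> 2   chrS  3850 3950      + gene003         53 1.0000000    3UTR
#> 74  chrS  5049 5149      - gene004         44 0.6666667    3UTR
#> 73  chrS  4849 4949      - gene004         22 0.3333333    3UTR
#> 3   chrS  7050 7150      + gene005         11 0.1692308    3UTR

site_recovery(ref$truth$pas, build_pas_windows(events))$fraction
#> recovered 100.0% of the 149 planted sites

motif_enrichment_test(pau, ref$genome, "AATAAA")
#> AATAAA in [-30,-20] vs [+20,+30]: OR = 88209, p = 1.7e-88
```

Each row is one PAS site: a 100-nt window ending at the cleavage
coordinate, the number of polyA reads supporting it, and its usage within
the gene (`gene004` splits 2:1 between its distal and proximal site). The
enrichment line reproduces the classic signal-site signature ~20–30 nt
upstream of called cleavage sites.

A command-line veneer over the same functions is installed at
`inst/scripts/polyacall`:

```sh
polyacall simulate --seed 3 --outdir fx
polyacall filter --bam fx/reads.sam --genome fx/ref.fa --out fx/events.tsv
polyacall call-isoseq --events fx/events.tsv --bam fx/reads.sam \
    --gtf fx/genes.gtf --out fx/pas.bed
polyacall qtl --pheno fx/pau.tsv --vcf fx/geno.vcf --perm 1000 --seed 3
```

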