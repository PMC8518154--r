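# Shared simulated fixtures, built once per test session.

.fixtures <- new.env(parent = emptyenv())

# Small end-to-end long-read fixture (12 genes) for module tests.
small_fixture <- function() {
  if (!is.null(.fixtures$small)) return(.fixtures$small)
  cfg <- sim_config(seed = 11, n_genes = 12L)
  ref <- simulate_reference(cfg)
  reads <- simulate_long_reads(cfg, ref)
  sam <- tempfile(fileext = ".sam")
  write_sam(reads, ref$genome, sam)
  al <- parse_alignments(sam)
  ev <- extract_cleavage_events(al, ref$genome, mode = "longread")
  cand <- build_pas_windows(ev)
  sites <- assign_and_filter(cand, ev, ref$gene_models)
  .fixtures$small <- list(cfg = cfg, ref = ref, reads = reads, sam = sam,
                          alignments = al, events = ev, candidates = cand,
                          sites = sites)
  .fixtures$small
}

# A tiny literal genome for hand-crafted flank tests.
toy_genome <- function(seq, chrom = "chrT") {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- chrom
  g
}
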