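# The synthetic-data generator: determinism, planted structure, truth labels.

test_that("identical configs reproduce byte-identical reference fixtures", {
  cfg <- sim_config(seed = 4, n_genes = 8L)
  fa1 <- tempfile(fileext = ".fa"); fa2 <- tempfile(fileext = ".fa")
  gtf1 <- tempfile(fileext = ".gtf"); gtf2 <- tempfile(fileext = ".gtf")
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  Biostrings::writeXStringSet(r1$genome, fa1)
  Biostrings::writeXStringSet(r2$genome, fa2)
  write_gene_models(r1$gene_models, gtf1)
  write_gene_models(r2$gene_models, gtf2)
  expect_identical(readLines(fa1), readLines(fa2))
  expect_identical(readLines(gtf1), readLines(gtf2))
  expect_identical(r1$truth, r2$truth)
  # and the downstream read/coverage draws
  expect_identical(simulate_long_reads(cfg, r1)$tail,
                   simulate_long_reads(cfg, r2)$tail)
  expect_identical(simulate_3seq(cfg, r1)$tracks[["+"]]$counts,
                   simulate_3seq(cfg, r2)$tracks[["+"]]$counts)
})

test_that("every planted site carries its signal elements and clean flanks", {
  cfg <- sim_config(seed = 4, n_genes = 10L)
  ref <- simulate_reference(cfg)
  g <- as.character(ref$genome)[[1]]
  pas <- ref$truth$pas
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  for (i in seq_len(nrow(pas))) {
    p <- pas$position[i]
    if (pas$strand[i] == "+") {
      expect_equal(substr(g, p - 24, p - 19), "AATAAA")   # offset -25
      down <- substr(g, p + 2, p + 11)
    } else {
      expect_equal(rc(substr(g, p + 21, p + 26)), "AATAAA")
      down <- rc(substr(g, p - 9, p))
    }
    expect_lt(brute_longest_a_run(down), 6)
  }
})

test_that("decoys are the only long genomic A-stretches in the 3' UTRs", {
  cfg0 <- sim_config(seed = 4, n_genes = 10L, decoy_fraction = 0)
  ref0 <- simulate_reference(cfg0)
  expect_equal(nrow(ref0$truth$decoys), 0L)
  g <- as.character(ref0$genome)[[1]]
  gm <- ref0$gene_models$genes
  for (i in seq_len(nrow(gm))) {
    utr <- substr(g, gm$utr3_start[i] + 1, gm$utr3_end[i])
    expect_lt(brute_longest_a_run(utr), 6)
    expect_lt(brute_longest_a_run(chartr("ACGT", "TGCA", utr)), 6)
  }
  cfg1 <- sim_config(seed = 4, n_genes = 10L, decoy_fraction = 1)
  ref1 <- simulate_reference(cfg1)
  expect_equal(nrow(ref1$truth$decoys), 10L)
})

test_that("error-free tails always classify as polyA tails", {
  cfg <- sim_config(seed = 6, n_genes = 6L, tail_error_rate = 0,
                    notail_fraction = 0, misprime_fraction = 0)
  ref <- simulate_reference(cfg)
  reads <- simulate_long_reads(cfg, ref)
  ok <- vapply(reads$tail, function(s) classify_polya_tail(s)$has_tail, FALSE)
  expect_true(all(ok))
})

test_that("read site choice follows the planted usage composition", {
  fx <- small_fixture()
  pas <- fx$ref$truth$pas
  reads <- fx$reads[fx$reads$true_class == "tail", ]
  for (gid in unique(pas$gene_id)[1:5]) {
    gp <- pas[pas$gene_id == gid, ]
    if (nrow(gp) < 2) next
    sel <- reads$true_gene == gid
    n <- sum(sel)
    emp <- tabulate(reads$true_site[sel], nbins = nrow(gp)) / n
    bound <- 2.576 * sqrt(gp$true_pau * (1 - gp$true_pau) / n)
    expect_true(all(abs(emp - gp$true_pau) <= bound + 0.08))
  }
})

test_that("3'-Seq coverage modes sit at the planted positions", {
  cfg <- sim_config(seed = 9, n_genes = 6L, background_rate = 0,
                    max_sites_per_gene = 1L)
  ref <- simulate_reference(cfg)
  ts <- simulate_3seq(cfg, ref)
  for (strand in names(ts$tracks)) {
    trk <- ts$tracks[[strand]]
    pas <- ts$truth[ts$truth$strand == strand, ]
    for (i in seq_len(nrow(pas))) {
      pos_range <- (pas$position[i] - 50L):(pas$position[i] + 50L)
      idx <- pos_range - trk$offset + 1L
      ok <- idx >= 1 & idx <= length(trk$counts)
      pos_range <- pos_range[ok]; idx <- idx[ok]
      # smooth with a 7-base running sum; single-base counts are sparse
      sm <- stats::filter(trk$counts[idx], rep(1, 7), sides = 2)
      mode_pos <- pos_range[which.max(sm)]
      expect_lte(abs(mode_pos - pas$position[i]), cfg$peak_sigma)
    }
  }
})

test_that("QTL cohort usages are compositions and genotype files round trip", {
  cfg <- sim_config(seed = 15, n_samples = 25L)
  co <- simulate_qtl_cohort(cfg, n_sites = 12L)
  expect_true(all(abs(co$pau + co$pau_proximal - 1) < 1e-12))
  expect_true(all(co$geno$dosage %in% 0:2))
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(co$geno, vcf)
  back <- read_genotypes(vcf)
  ord <- match(colnames(co$geno$dosage), colnames(back$dosage))
  expect_equal(unname(back$dosage[, ord]), unname(co$geno$dosage))
  expect_equal(back$variants$position[ord], co$geno$variants$position)
  # PAU matrix TSV round trip
  tsv <- tempfile(fileext = ".tsv")
  write_pau_matrix(co$pau, co$site_meta, tsv)
  back2 <- read_pau_matrix(tsv)
  expect_equal(back2$site_meta$site_id, co$site_meta$site_id)
  expect_equal(unname(back2$pau), unname(co$pau), tolerance = 1e-12)
})

test_that("a null cohort gives uniform scan p-values and R2 controls the correlation", {
  cfg <- sim_config(seed = 61, n_samples = 50, planted_qtl_fraction = 0)
  co <- simulate_qtl_cohort(cfg, n_sites = 40)
  nom <- cis_scan(quantile_normalize(co$pau), co$site_meta, co$geno)
  expect_gt(suppressWarnings(ks.test(nom$p, "punif"))$p.value, 0.01)
})
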