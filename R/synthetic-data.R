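# Synthetic data with planted ground truth: a toy genome with annotated
# genes and 3' UTRs, long reads carrying non-templated polyA tails (plus
# mispriming decoys on genomically templated A-stretches), 3'-Seq read-end
# coverage with planted peaks, and QTL cohorts with genotype-linked usage
# shifts.  Every generator takes an explicit seed and derives per-stage
# child seeds, so fixtures are reproducible and stable when one stage's
# draw count changes.

#' Simulation configuration
#'
#' Defaults describe the study conditions the rest of the package is
#' validated under: 50 genes with 1-5 PAS sites each (usage drawn from a
#' symmetric Dirichlet), 80 long reads per gene of which 10% are internally
#' primed at genomic A-stretch decoys and 5% carry no tail, polyA tails of
#' mean length 30 nt with 2% per-base impurity (80 reads leaves every gene
#' above the 40-polyA-read coverage filter after the tail-purity and
#' mispriming losses), 3'-Seq peaks of bandwidth
#' 10 nt over 6 libraries at 30 reads/library/site, and cohorts of 60
#' samples with planted cis effects of R^2 = 0.2.
#'
#' @param seed master RNG seed (mandatory).
#' @param n_genes number of genes.
#' @param max_sites_per_gene PAS sites per gene drawn uniformly from
#'   `1:max_sites_per_gene`.
#' @param pau_dirichlet_alpha symmetric Dirichlet concentration for true
#'   usages.
#' @param reads_per_gene long reads simulated per gene.
#' @param tail_length_mean mean polyA tail length (nt; 5 + Poisson).
#' @param tail_error_rate per-base non-A substitution rate in tails.
#' @param misprime_fraction fraction of reads internally primed at a decoy
#'   (in genes carrying one).
#' @param notail_fraction fraction of reads without a soft-clipped tail.
#' @param decoy_fraction fraction of genes with a genomic A-stretch decoy in
#'   their 3' UTR.
#' @param peak_sigma 3'-Seq cleavage scatter (nt, Gaussian).
#' @param threeseq_depth mean 3'-Seq reads per library per site at usage 1.
#' @param n_libraries 3'-Seq libraries pooled.
#' @param background_rate per-base Poisson background rate for 3'-Seq.
#' @param n_samples QTL cohort size.
#' @param variants_per_site candidate cis variants simulated per site.
#' @param planted_qtl_fraction fraction of genes given a genotype effect.
#' @param qtl_effect_r2 target fraction of latent usage variance explained
#'   by the planted dosage.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_genes = 50L,
                       max_sites_per_gene = 5L,
                       pau_dirichlet_alpha = 5,
                       reads_per_gene = 80L,
                       tail_length_mean = 30,
                       tail_error_rate = 0.02,
                       misprime_fraction = 0.10,
                       notail_fraction = 0.05,
                       decoy_fraction = 0.5,
                       peak_sigma = 10,
                       threeseq_depth = 30,
                       n_libraries = 6L,
                       background_rate = 0.02,
                       n_samples = 60L,
                       variants_per_site = 10L,
                       planted_qtl_fraction = 0.3,
                       qtl_effect_r2 = 0.2) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  g / sum(g)
}

# Draw a flank string of length n that cannot trigger the mispriming rules
# (< 6 A's in any 10-mer window and no A-run of length >= 4).
safe_flank <- function(n) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                      prob = c(0.10, 0.30, 0.30, 0.30)), collapse = "")
    if (longest_run(s, "A") >= 4L) next
    counts <- vapply(seq_len(max(1L, n - 9L)), function(i)
      count_letter(substr(s, i, min(i + 9L, n)), "A"), 0L)
    if (all(counts < 6L)) return(s)
  }
}

#' Simulate a reference genome with annotated genes and planted PAS sites
#'
#' Genes alternate strand along one chromosome; each has two exons, a CDS
#' and a 3' UTR carrying 1-5 planted PAS sites spaced 200 nt apart.  Every
#' planted site gets an `AATAAA` signal hexamer at offset -25 and a GT-rich
#' element at +15 (transcript orientation), and its mispriming flanks are
#' drawn A-poor so true cleavage events survive the filters.  A fraction of
#' genes carries a 13-nt genomic A-stretch decoy in the 3' UTR.
#'
#' @param config A [sim_config()].
#' @return list with `genome` ([Biostrings::DNAStringSet]), `gene_models`,
#'   and `truth`: data.frames `pas` (gene_id, site_index, chrom, strand,
#'   position, true_pau) and `decoys` (gene_id, chrom, strand, position).
#' @export
simulate_reference <- function(config) {
  set.seed(child_seed(config$seed, 1L))
  n <- config$n_genes
  k_sites <- sample.int(config$max_sites_per_gene, n, replace = TRUE)
  gap <- 600L; e1_len <- 300L; intron_len <- 200L; cds2_len <- 100L
  genes <- exons <- cds <- pas <- decoys <- list()
  cursor <- 200L
  seq_parts <- list(); part_cursor <- 0L
  chrom <- "chrS"
  for (i in seq_len(n)) {
    gid <- sprintf("gene%03d", i)
    strand <- if (i %% 2L == 1L) "+" else "-"
    k <- k_sites[i]
    utr_len <- 150L + 200L * (k - 1L) + 150L
    e2_len <- cds2_len + utr_len
    gstart <- cursor
    if (strand == "+") {
      e1 <- c(gstart, gstart + e1_len)
      e2 <- c(e1[2] + intron_len, e1[2] + intron_len + e2_len)
      cds_iv <- list(c(e1[1], e1[2]), c(e2[1], e2[1] + cds2_len))
      utr3 <- c(e2[1] + cds2_len, e2[2])
      pas_pos <- utr3[1] + 150L + 200L * (seq_len(k) - 1L)
    } else {
      # mirror: transcript runs right-to-left
      e2 <- c(gstart, gstart + e2_len)
      e1 <- c(e2[2] + intron_len, e2[2] + intron_len + e1_len)
      cds_iv <- list(c(e2[2] - cds2_len, e2[2]), c(e1[1], e1[2]))
      utr3 <- c(e2[1], e2[2] - cds2_len)
      pas_pos <- utr3[2] - 150L - 200L * (seq_len(k) - 1L) - 1L
    }
    gend <- max(e1[2], e2[2])
    true_pau <- rdirichlet1(k, config$pau_dirichlet_alpha)
    # order sites 5'->3' along the transcript
    genes[[i]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                             start = gstart, end = gend,
                             utr3_start = utr3[1], utr3_end = utr3[2],
                             stringsAsFactors = FALSE)
    exons[[i]] <- data.frame(gene_id = gid,
                             start = c(min(e1[1], e2[1]), max(e1[1], e2[1])),
                             end = c(min(e1[2], e2[2]), max(e1[2], e2[2])),
                             stringsAsFactors = FALSE)
    cds[[i]] <- data.frame(gene_id = gid,
                           start = vapply(cds_iv, `[`, 0L, 1L),
                           end = vapply(cds_iv, `[`, 0L, 2L),
                           stringsAsFactors = FALSE)
    pas[[i]] <- data.frame(gene_id = gid, site_index = seq_len(k),
                           chrom = chrom, strand = strand,
                           position = as.integer(pas_pos),
                           true_pau = true_pau, stringsAsFactors = FALSE)
    if (stats::runif(1) < config$decoy_fraction && k >= 1L) {
      dpos <- if (strand == "+") utr3[1] + 40L else utr3[2] - 53L
      decoys[[i]] <- data.frame(gene_id = gid, chrom = chrom,
                                strand = strand, position = as.integer(dpos),
                                stringsAsFactors = FALSE)
    }
    cursor <- gend + gap
  }
  genome_len <- cursor + 200L
  base <- sample(c("A", "C", "G", "T"), genome_len, replace = TRUE)
  pas_df <- do.call(rbind, pas)
  # plant signal elements and scrub mispriming flanks (coordinates 0-based;
  # vector index = position + 1)
  put <- function(pos0, s) {
    idx <- pos0 + seq_len(nchar(s))
    base[idx] <<- strsplit(s, "", fixed = TRUE)[[1]]
  }
  for (r in seq_len(nrow(pas_df))) {
    p <- pas_df$position[r]
    if (pas_df$strand[r] == "+") {
      put(p - 25L, "AATAAA")
      put(p + 15L, "GTGTGTGTGT")
      put(p - 10L, safe_flank(10L))          # upstream flank [p-10, p)
      put(p + 1L, safe_flank(12L))           # downstream flank [p+1, p+13)
      put(p, sample(c("C", "G", "T"), 1L))   # cleavage base itself
    } else {
      put(p + 20L, "TTTATT")                 # revcomp(AATAAA)
      put(p - 24L, "ACACACACAC")             # revcomp(GTGTGTGTGT)
      put(p + 1L, revcomp(safe_flank(10L)))  # upstream flank (transcript 5')
      put(p - 12L, revcomp(safe_flank(12L))) # downstream flank
      put(p, sample(c("C", "G", "A"), 1L))
    }
  }
  # break accidental A/T homopolymer runs of length >= 6 (before decoy
  # insertion) so the only mispriming decoys are the planted ones; the
  # planted signal hexamers are protected from substitution
  protected <- logical(genome_len)
  for (r in seq_len(nrow(pas_df))) {
    p <- pas_df$position[r]
    m <- if (pas_df$strand[r] == "+") (p - 25L):(p - 20L) else (p + 20L):(p + 25L)
    protected[m + 1L] <- TRUE
  }
  for (letter in c("A", "T")) {
    rl <- rle(base == letter)
    run_end <- cumsum(rl$lengths)
    for (j in which(rl$values & rl$lengths >= 6L)) {
      st <- run_end[j] - rl$lengths[j] + 1L
      pos <- st:run_end[j]
      while (length(pos) >= 6L) {
        # split so both pieces are shorter than 6; avoid protected bases
        cand <- pos[seq.int(max(1L, length(pos) - 5L), min(6L, length(pos)))]
        cand <- cand[!protected[cand]]
        if (length(cand) == 0L) break
        brk <- cand[length(cand)]
        base[brk] <- if (letter == "A") "C" else "G"
        pos <- pos[pos > brk]
      }
    }
  }
  decoy_df <- if (length(decoys)) do.call(rbind, decoys) else
    data.frame(gene_id = character(), chrom = character(),
               strand = character(), position = integer())
  for (r in seq_len(nrow(decoy_df))) {
    if (decoy_df$strand[r] == "+") put(decoy_df$position[r], strrep("A", 13L))
    else put(decoy_df$position[r] - 12L, strrep("T", 13L))
  }
  genome <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(genome) <- chrom
  gm <- structure(list(genes = do.call(rbind, genes),
                       exons = do.call(rbind, exons)),
                  class = "gene_models")
  gm$genes$utr5_start <- NA_integer_; gm$genes$utr5_end <- NA_integer_
  list(genome = genome, gene_models = gm, cds = do.call(rbind, cds),
       truth = list(pas = pas_df, decoys = decoy_df))
}

#' Simulate long reads with polyA tails as SAM-style alignment records
#'
#' Per gene, `reads_per_gene` reads each pick a planted PAS with probability
#' equal to its true usage, start at a random position in the upstream exon
#' and run through the cleavage site (one spliced junction).  A polyA tail
#' with the configured length distribution and per-base impurity is appended
#' as a soft clip.  In genes carrying a decoy, `misprime_fraction` of reads
#' instead end at the genomic A-stretch with a templated-A soft clip;
#' `notail_fraction` of reads carry no soft clip at all.
#'
#' @param config A [sim_config()].
#' @param ref output of [simulate_reference()].
#' @return list with `reads` (the [parse_alignments()] layout plus truth
#'   columns `true_site`, `true_class` in tail/misprime/notail) and the
#'   per-read SAM fields needed by [write_sam()].
#' @export
simulate_long_reads <- function(config, ref) {
  set.seed(child_seed(config$seed, 2L))
  gm <- ref$gene_models
  pas <- ref$truth$pas
  decoys <- ref$truth$decoys
  rows <- list()
  for (gi in seq_len(nrow(gm$genes))) {
    g <- gm$genes[gi, ]
    gp <- pas[pas$gene_id == g$gene_id, , drop = FALSE]
    has_decoy <- g$gene_id %in% decoys$gene_id
    dpos <- if (has_decoy) decoys$position[decoys$gene_id == g$gene_id] else NA
    e <- gm$exons[gm$exons$gene_id == g$gene_id, , drop = FALSE]
    # upstream exon in transcript orientation
    up_exon <- if (g$strand == "+") unlist(e[1, c("start", "end")])
               else unlist(e[nrow(e), c("start", "end")])
    for (ri in seq_len(config$reads_per_gene)) {
      u <- stats::runif(1)
      cls <- if (has_decoy && u < config$misprime_fraction) "misprime"
             else if (u < config$misprime_fraction + config$notail_fraction &&
                      !(has_decoy && u < config$misprime_fraction)) "notail"
             else "tail"
      if (!has_decoy && u < config$misprime_fraction) cls <- "tail"
      site <- sample.int(nrow(gp), 1L, prob = gp$true_pau)
      end_pos <- if (cls == "misprime") dpos else gp$position[site]
      tail <- ""
      if (cls == "tail") {
        tl <- 5L + stats::rpois(1, config$tail_length_mean - 5)
        bases <- rep("A", tl)
        err <- stats::runif(tl) < config$tail_error_rate
        if (any(err))
          bases[err] <- sample(c("C", "G", "T"), sum(err), replace = TRUE)
        tail <- paste(bases, collapse = "")
      } else if (cls == "misprime") {
        tail <- strrep("A", 10L)
      }
      if (g$strand == "+") {
        rstart <- up_exon[1] + sample.int(up_exon[2] - up_exon[1] - 50L, 1L)
        blocks <- rbind(c(rstart, up_exon[2]),
                        c(e$start[2], end_pos))
      } else {
        rend <- up_exon[2] - sample.int(up_exon[2] - up_exon[1] - 50L, 1L)
        blocks <- rbind(c(end_pos + 1L, e$end[1]),
                        c(up_exon[1], rend))
      }
      rows[[length(rows) + 1L]] <- list(
        read_id = sprintf("%s_r%03d", g$gene_id, ri),
        chrom = g$chrom, strand = g$strand, blocks = blocks,
        tail = tail, true_class = cls,
        true_site = if (cls == "misprime") NA_integer_ else site,
        true_gene = g$gene_id)
    }
  }
  reads <- data.frame(
    read_id = vapply(rows, `[[`, "", "read_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    true_class = vapply(rows, `[[`, "", "true_class"),
    true_site = vapply(rows, `[[`, 0L, "true_site"),
    true_gene = vapply(rows, `[[`, "", "true_gene"),
    tail = vapply(rows, `[[`, "", "tail"),
    stringsAsFactors = FALSE)
  reads$blocks <- lapply(rows, `[[`, "blocks")
  reads
}

#' Write simulated reads as a SAM file
#'
#' Constructs CIGAR/SEQ from the truth blocks and tail; minus-strand records
#' get the tail reverse-complemented as a leading soft clip, as an aligner
#' would report it.
#'
#' @param reads data.frame from [simulate_long_reads()].
#' @param genome the reference the reads were simulated from.
#' @param path output SAM path.
#' @export
write_sam <- function(reads, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(genome), "\tLN:",
                  if (is.character(genome)) nchar(genome)
                  else Biostrings::width(genome)))
  genome <- as_genome_chars(genome)
  recs <- character(nrow(reads))
  ord <- order(reads$chrom,
               vapply(reads$blocks, function(b) b[1, 1], 0))
  reads <- reads[ord, , drop = FALSE]
  for (i in seq_len(nrow(reads))) {
    b <- reads$blocks[[i]]
    aligned <- paste0(vapply(seq_len(nrow(b)), function(j)
      genome_slice(genome, reads$chrom[i], b[j, 1], b[j, 2]), ""),
      collapse = "")
    mcig <- character(0)
    for (j in seq_len(nrow(b))) {
      mcig <- c(mcig, paste0(b[j, 2] - b[j, 1], "M"))
      if (j < nrow(b)) mcig <- c(mcig, paste0(b[j + 1, 1] - b[j, 2], "N"))
    }
    tail <- reads$tail[i]
    if (reads$strand[i] == "+") {
      cigar <- paste0(paste(mcig, collapse = ""),
                      if (nzchar(tail)) paste0(nchar(tail), "S") else "")
      seq <- paste0(aligned, tail)
      flag <- 0L
    } else {
      cigar <- paste0(if (nzchar(tail)) paste0(nchar(tail), "S") else "",
                      paste(mcig, collapse = ""))
      seq <- paste0(revcomp(tail), aligned)
      flag <- 16L
    }
    recs[i] <- paste(reads$read_id[i], flag, reads$chrom[i], b[1, 1] + 1L,
                     60L, cigar, "*", 0L, 0L, seq, "*", sep = "\t")
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Simulate 3'-Seq read-end coverage with planted peaks
#'
#' Read ends scatter around each planted PAS position as a discretized
#' Gaussian; per-library counts are Poisson with mean
#' `threeseq_depth * true_pau`, and a uniform Poisson background is added
#' over each gene span.  Libraries get derived sub-seeds, so tracks differ
#' across libraries but reproduce exactly for a given master seed.
#'
#' @param config A [sim_config()].
#' @param ref output of [simulate_reference()].
#' @return list with `events` (pooled per-strand end-position data.frames),
#'   `tracks` (pooled per-strand `coverage_track`s), and `truth` (the
#'   planted `pas` table with `expected_mean_support` added).
#' @export
simulate_3seq <- function(config, ref) {
  pas <- ref$truth$pas
  gm <- ref$gene_models$genes
  ends <- list()
  for (lib in seq_len(config$n_libraries)) {
    set.seed(child_seed(config$seed, 100L + lib))
    for (r in seq_len(nrow(pas))) {
      cnt <- stats::rpois(1, config$threeseq_depth * pas$true_pau[r])
      if (cnt == 0L) next
      pos <- as.integer(round(stats::rnorm(cnt, pas$position[r],
                                           config$peak_sigma)))
      ends[[length(ends) + 1L]] <- data.frame(
        chrom = pas$chrom[r], strand = pas$strand[r], position = pos,
        library = lib, stringsAsFactors = FALSE)
    }
    # background over gene spans
    for (gi in seq_len(nrow(gm))) {
      g <- gm[gi, ]
      span <- g$end - g$start
      nbg <- stats::rpois(1, config$background_rate * span)
      if (nbg == 0L) next
      ends[[length(ends) + 1L]] <- data.frame(
        chrom = g$chrom, strand = g$strand,
        position = g$start + sample.int(span, nbg, replace = TRUE) - 1L,
        library = lib, stringsAsFactors = FALSE)
    }
  }
  ev <- do.call(rbind, ends)
  tracks <- lapply(split(ev, ev$strand), compute_end_coverage)
  pas$expected_mean_support <- config$threeseq_depth * pas$true_pau
  list(events = ev, tracks = tracks, truth = pas)
}

#' Simulate a QTL cohort with planted genotype-to-usage effects
#'
#' Stands alone from the genomic simulation: sites are the distal PAS of
#' two-site genes at arbitrary coordinates (or supplied).  Dosages are
#' Binomial(2, f) with f ~ U(0.1, 0.5); for planted sites the distal usage
#' is shifted linearly in dosage on the logit scale to reach the target
#' latent R^2, with logit-normal noise; per-gene usages renormalize to 1.
#'
#' @param config A [sim_config()] (fields n_samples, variants_per_site,
#'   planted_qtl_fraction, qtl_effect_r2, seed).
#' @param n_sites number of (distal) sites to simulate.
#' @param base_pau mean distal usage before noise.
#' @param noise_sd logit-scale residual standard deviation.
#' @param maf_range allele-frequency range variants are drawn from
#'   (uniform); collapse to a single value to fix the MAF.
#' @return list with `pau` (samples x sites matrix of distal usages),
#'   `pau_proximal` (complements), `site_meta`, `geno` (as
#'   [read_genotypes()]), and `truth` (per-site planted flag, variant and
#'   target R^2).
#' @export
simulate_qtl_cohort <- function(config, n_sites = 50L, base_pau = 0.5,
                                noise_sd = 1, maf_range = c(0.1, 0.5)) {
  set.seed(child_seed(config$seed, 3L))
  n <- config$n_samples
  m <- config$variants_per_site
  planted <- stats::runif(n_sites) < config$planted_qtl_fraction
  pau <- matrix(NA_real_, n, n_sites)
  dosage <- NULL
  vrows <- list()
  truth <- list()
  site_meta <- data.frame(site_id = sprintf("site%03d", seq_len(n_sites)),
                          chrom = "chrS",
                          position = 50000L * seq_len(n_sites),
                          gene_id = sprintf("gene%03d", seq_len(n_sites)),
                          stringsAsFactors = FALSE)
  for (s in seq_len(n_sites)) {
    f <- stats::runif(m, maf_range[1], maf_range[2])
    G <- vapply(f, function(ff) stats::rbinom(n, 2L, ff), numeric(n))
    vid <- sprintf("%s_v%02d", site_meta$site_id[s], seq_len(m))
    vpos <- site_meta$position[s] +
      sample.int(40001L, m, replace = TRUE) - 20001L
    dosage <- cbind(dosage, G)
    vrows[[s]] <- data.frame(variant_id = vid, chrom = "chrS",
                             position = vpos, stringsAsFactors = FALSE)
    eps <- stats::rnorm(n, 0, noise_sd)
    latent <- stats::qlogis(base_pau) + eps
    beta <- 0; pv <- NA_character_
    if (planted[s]) {
      vi <- sample.int(m, 1L)
      pv <- vid[vi]
      g <- G[, vi]
      r2 <- config$qtl_effect_r2
      beta <- sqrt(r2 / (1 - r2)) * noise_sd / stats::sd(g)
      latent <- latent + beta * (g - mean(g))
    }
    pau[, s] <- stats::plogis(latent)
    truth[[s]] <- data.frame(site_id = site_meta$site_id[s],
                             planted = planted[s], variant = pv,
                             beta = beta, stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, vrows)
  colnames(dosage) <- variants$variant_id
  rownames(dosage) <- sprintf("S%03d", seq_len(n))
  rownames(pau) <- rownames(dosage)
  colnames(pau) <- site_meta$site_id
  af <- colMeans(dosage) / 2
  variants$maf <- pmin(af, 1 - af)
  list(pau = pau, pau_proximal = 1 - pau, site_meta = site_meta,
       geno = list(dosage = dosage, variants = variants),
       truth = do.call(rbind, truth))
}

#' Write a genotype matrix to VCF
#'
#' @param geno list as in [read_genotypes()].
#' @param path output VCF path.
#' @export
write_vcf <- function(geno, path) {
  samples <- rownames(geno$dosage)
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chrS,length=100000000>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  gts <- c("0/0", "0/1", "1/1")
  o <- order(geno$variants$position)
  lines <- vapply(o, function(v) {
    d <- geno$dosage[, v]
    gt <- ifelse(is.na(d), "./.", gts[d + 1L])
    paste(c(geno$variants$chrom[v], geno$variants$position[v] + 1L,
            geno$variants$variant_id[v], "A", "G", ".", "PASS", ".",
            "GT", gt), collapse = "\t")
  }, "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write a PAU phenotype matrix to TSV
#'
#' Layout: one row per site with a 4-column header (site_id, chrom,
#' position, gene_id) followed by one column per sample.
#'
#' @param pau samples x sites matrix.
#' @param site_meta data.frame with site_id, chrom, position, gene_id.
#' @param path output path.
#' @export
write_pau_matrix <- function(pau, site_meta, path) {
  df <- cbind(site_meta[, c("site_id", "chrom", "position", "gene_id")],
              t(pau))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PAU phenotype matrix written by [write_pau_matrix()]
#'
#' @param path TSV path.
#' @return list with `pau` (samples x sites) and `site_meta`.
#' @export
read_pau_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta <- df[, 1:4]
  mat <- t(as.matrix(df[, -(1:4), drop = FALSE]))
  colnames(mat) <- meta$site_id
  list(pau = mat, site_meta = meta)
}
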