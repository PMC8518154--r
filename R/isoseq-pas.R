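# From cleavage events to PAS sites with per-gene usage (PAU).
#
# A PAS site is the 100-nt window ending at the cleavage position:
# [position - 100, position) on '+', [position, position + 100) on '-'.
# Overlapping same-strand windows are merged and their read counts pooled
# (alternatively, cleavage positions can be clustered within a fixed
# distance before windowing; see `merge`).

#' Build candidate PAS windows from cleavage events
#'
#' @param events data.frame from [extract_cleavage_events()].
#' @param merge `"overlap"` merges overlapping same-strand windows;
#'   `"cluster"` instead clusters cleavage positions within `cluster_nt`.
#' @param cluster_nt clustering distance for `merge = "cluster"`.
#' @param chrom_sizes optional named vector of chromosome lengths used to
#'   truncate windows at chromosome ends (with a warning).
#' @return data.frame of candidate sites: chrom, strand, start, end,
#'   read_count, cleavage_pos (3'-most supported cleavage position) and a
#'   list-column `event_idx` of indices into `events`.
#' @export
build_pas_windows <- function(events, merge = c("overlap", "cluster"),
                              cluster_nt = 24L, chrom_sizes = NULL) {
  merge <- match.arg(merge)
  empty <- data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      read_count = integer(), cleavage_pos = integer(),
                      stringsAsFactors = FALSE)
  empty$event_idx <- list()
  if (nrow(events) == 0L) return(empty)
  win_start <- ifelse(events$strand == "+", events$position - 100L,
                      events$position)
  win_end <- win_start + 100L
  out <- list()
  for (key in unique(paste(events$chrom, events$strand))) {
    sel <- which(paste(events$chrom, events$strand) == key)
    ev <- events[sel, , drop = FALSE]
    if (merge == "overlap") {
      ir <- IRanges::IRanges(start = win_start[sel] + 1L, end = win_end[sel])
      red <- IRanges::reduce(ir)
      hit <- IRanges::findOverlaps(ir, red, select = "first")
      groups <- split(seq_along(sel), hit)
      starts <- BiocGenerics::start(red) - 1L
      ends <- BiocGenerics::end(red)
    } else {
      o <- order(ev$position)
      gaps <- c(Inf, diff(ev$position[o]))
      grp <- cumsum(gaps > cluster_nt)
      groups <- split(o, grp)
      starts <- ends <- integer(length(groups))
      for (g in seq_along(groups)) {
        p <- ev$position[groups[[g]]]
        if (ev$strand[1] == "+") {
          starts[g] <- min(p) - 100L; ends[g] <- max(p)
        } else {
          starts[g] <- min(p); ends[g] <- max(p) + 100L
        }
      }
    }
    for (g in seq_along(groups)) {
      idx <- sel[groups[[g]]]
      cp <- if (ev$strand[1] == "+") max(events$position[idx])
            else min(events$position[idx])
      out[[length(out) + 1L]] <- data.frame(
        chrom = ev$chrom[1], strand = ev$strand[1],
        start = as.integer(starts[g]), end = as.integer(ends[g]),
        read_count = length(idx), cleavage_pos = as.integer(cp),
        stringsAsFactors = FALSE)
      out[[length(out)]]$event_idx <- list(idx)
    }
  }
  res <- do.call(rbind, out)
  if (!is.null(chrom_sizes)) {
    trunc <- res$start < 0L |
      res$end > chrom_sizes[res$chrom]
    if (any(trunc, na.rm = TRUE)) {
      warning(sum(trunc, na.rm = TRUE), " window(s) truncated at chromosome ends")
      res$start <- pmax(res$start, 0L)
      known <- !is.na(chrom_sizes[res$chrom])
      res$end[known] <- pmin(res$end[known], chrom_sizes[res$chrom][known])
    }
  } else {
    res$start <- pmax(res$start, 0L)
  }
  res[order(res$chrom, res$start), , drop = FALSE]
}

# Exonic region of a gene 5' of its 3' UTR, as a 2-col matrix of 0-based
# half-open intervals; empty matrix when no 3' UTR.
upstream_exonic <- function(gene, exons) {
  if (is.na(gene$utr3_start)) return(matrix(integer(0), ncol = 2))
  e <- exons[exons$gene_id == gene$gene_id, , drop = FALSE]
  if (gene$strand == "+") {
    keep <- e$start < gene$utr3_start
    cbind(e$start[keep], pmin(e$end[keep], gene$utr3_start))
  } else {
    keep <- e$end > gene$utr3_end
    cbind(pmax(e$start[keep], gene$utr3_end), e$end[keep])
  }
}

blocks_overlap <- function(blocks, region) {
  if (nrow(region) == 0L || is.null(blocks) || nrow(blocks) == 0L) return(FALSE)
  for (i in seq_len(nrow(blocks)))
    for (j in seq_len(nrow(region)))
      if (blocks[i, 1] < region[j, 2] && region[j, 1] < blocks[i, 2])
        return(TRUE)
  FALSE
}

#' Assign PAS sites to genes and genic contexts
#'
#' Each site is assigned to the same-strand gene whose span overlaps its
#' window; ties are broken in favour of a gene whose annotated 3' UTR
#' contains the cleavage position, then by proximity of the annotated
#' transcript 3' end.  The genic context of the cleavage position is
#' labelled 3UTR/5UTR/exon/intron; sites overlapping no gene are labelled
#' intergenic and dropped.  A 3' UTR site is retained only when at least one
#' supporting read has an aligned block overlapping exonic sequence upstream
#' of that 3' UTR.
#'
#' @param sites data.frame from [build_pas_windows()].
#' @param events the cleavage events the sites were built from (supplies the
#'   supporting reads' aligned blocks).
#' @param gene_models A `gene_models` object.
#' @param require_upstream_exon apply the 3' UTR upstream-exon rule; set to
#'   `FALSE` for inputs without per-read alignment blocks (3'-Seq peaks).
#' @return `sites` with columns `gene_id` and `context` added; intergenic
#'   sites and 3' UTR sites failing the upstream-exon rule removed.
#' @export
assign_and_filter <- function(sites, events, gene_models,
                              require_upstream_exon = TRUE) {
  genes <- gene_models$genes; exons <- gene_models$exons
  if (nrow(sites) == 0L) {
    sites$gene_id <- character(0); sites$context <- character(0)
    return(sites)
  }
  gene_id <- rep(NA_character_, nrow(sites))
  context <- rep("intergenic", nrow(sites))
  keep <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    cand <- genes[genes$chrom == s$chrom & genes$strand == s$strand &
                    genes$start < s$end & genes$end > s$start, , drop = FALSE]
    if (nrow(cand) == 0L) next
    if (nrow(cand) > 1L) {
      in_utr <- !is.na(cand$utr3_start) &
        cand$utr3_start <= s$cleavage_pos & s$cleavage_pos < cand$utr3_end
      if (any(in_utr)) {
        cand <- cand[in_utr, , drop = FALSE]
      } else {
        tts <- ifelse(cand$strand == "+", cand$end, cand$start)
        cand <- cand[order(abs(tts - s$cleavage_pos)), , drop = FALSE]
      }
    }
    g <- cand[1, ]
    gene_id[i] <- g$gene_id
    cp <- s$cleavage_pos
    e <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    in_exon <- any(e$start <= cp & cp < e$end)
    context[i] <-
      if (!is.na(g$utr3_start) && g$utr3_start <= cp && cp < g$utr3_end) "3UTR"
      else if (!is.na(g$utr5_start) && g$utr5_start <= cp && cp < g$utr5_end) "5UTR"
      else if (in_exon) "exon"
      else "intron"
    if (context[i] == "3UTR" && require_upstream_exon) {
      region <- upstream_exonic(g, exons)
      idx <- sites$event_idx[[i]]
      keep[i] <- any(vapply(idx, function(k)
        blocks_overlap(events$blocks[[k]], region), FALSE))
    } else keep[i] <- TRUE
  }
  sites$gene_id <- gene_id
  sites$context <- context
  sites[keep & !is.na(gene_id), , drop = FALSE]
}

#' Quantify polyadenylation site usage per gene
#'
#' PAU of a site is its read count divided by the total read count over all
#' PAS sites of the same gene (computed before any filtering).  Genes with
#' fewer than `min_gene_reads` total reads are dropped entirely; sites with
#' PAU less than or equal to `min_pau` are then dropped without rescaling
#' the remaining usages.
#'
#' @param sites data.frame with gene_id and read_count (from
#'   [assign_and_filter()]).
#' @param min_gene_reads minimum total polyA reads per gene (inclusive).
#' @param min_pau usage cut; sites must exceed it strictly (`min_pau = 0`
#'   keeps every site).
#' @return A `pau_table`: the site table with `pau` and `gene_read_total`
#'   columns, sites ordered 5'->3' in transcript orientation within gene.
#' @export
quantify_pau <- function(sites, min_gene_reads = 40L, min_pau = 0.05) {
  if (min_pau < 0 || min_pau >= 1)
    stop("min_pau must lie in [0, 1)", call. = FALSE)
  tot <- tapply(sites$read_count, sites$gene_id, sum)
  sites$gene_read_total <- as.integer(tot[sites$gene_id])
  sites$pau <- sites$read_count / sites$gene_read_total
  sites <- sites[sites$gene_read_total >= min_gene_reads, , drop = FALSE]
  sites <- sites[sites$pau > min_pau, , drop = FALSE]
  tx_pos <- ifelse(sites$strand == "+", sites$end, -sites$start)
  sites <- sites[order(sites$gene_id, tx_pos), , drop = FALSE]
  sites$name <- if (nrow(sites) == 0L) character(0) else
    paste0(sites$gene_id, ":",
           stats::ave(seq_len(nrow(sites)), sites$gene_id, FUN = seq_along))
  class(sites) <- c("pau_table", "data.frame")
  sites
}

#' Rescale PAU to sum to one over retained sites
#'
#' Used when sites are omitted (e.g. unannotatable ones), so the per-gene
#' usages again form a composition.
#'
#' @param table A `pau_table`.
#' @return The table with `pau` renormalized per gene; genes whose retained
#'   usage sums to zero are removed with a warning.
#' @export
rescale_pau <- function(table) {
  tot <- tapply(table$pau, table$gene_id, sum)
  zero <- names(tot)[tot <= 0]
  if (length(zero) > 0L) {
    warning("gene(s) with zero retained usage removed: ",
            paste(zero, collapse = ", "))
    table <- table[!table$gene_id %in% zero, , drop = FALSE]
  }
  table$pau <- table$pau / as.numeric(tot[table$gene_id])
  table
}

#' @export
print.pau_table <- function(x, ...) {
  cat(sprintf("pau_table: %d PAS sites in %d genes\n",
              nrow(x), length(unique(x$gene_id))))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(
    x[, intersect(c("chrom", "start", "end", "strand", "gene_id",
                    "read_count", "pau", "context"), names(x))]), 6))
  invisible(x)
}
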