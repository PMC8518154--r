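# Readers/writers for the standard formats and the shared genomic data model.
#
# Coordinate convention: every interval in this package is 0-based, half-open
# [start, end).  BED files are emitted in the same convention; GTF (1-based,
# closed) is converted on read and write.

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] with uppercase sequences, one element
#'   per chromosome.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  Biostrings::DNAStringSet(toupper(g))
}

#' Parse long-read alignments into transcript-oriented 3' soft-clip records
#'
#' Each primary alignment yields one record with the soft clip past the
#' transcript-3' end of the alignment, oriented 5'->3' along the transcript
#' (reverse-complemented for minus-strand records).  Unmapped, secondary and
#' supplementary records are skipped.
#'
#' @param path SAM or BAM file (SAM is converted to a temporary BAM).
#' @param min_clip_report minimum soft-clip length to report; shorter clips
#'   are returned as empty strings.
#' @return data.frame with columns `read_id`, `chrom`, `strand`, `clip3_seq`,
#'   `clip3_ref_pos` (0-based: rightmost block end for `+`, leftmost block
#'   start for `-`) and a list-column `blocks` of 2-column matrices of
#'   0-based half-open aligned reference blocks.
#' @export
parse_alignments <- function(path, min_clip_report = 0L) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("qname", "rname", "strand", "pos", "cigar", "seq"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(rec$qname)
  if (n == 0L) {
    return(data.frame(read_id = character(), chrom = character(),
                      strand = character(), clip3_seq = character(),
                      clip3_ref_pos = integer(),
                      blocks = I(list()), stringsAsFactors = FALSE))
  }
  allseq <- as.character(rec$seq)
  keep <- !is.na(allseq) & nzchar(allseq) & allseq != "*"
  if (any(!keep))
    warning(sum(!keep), " record(s) without sequence skipped")
  cigar <- rec$cigar
  bad <- is.na(cigar) | !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
  if (any(bad & keep))
    stop("malformed CIGAR for read(s): ",
         paste(utils::head(rec$qname[bad & keep], 5), collapse = ", "),
         call. = FALSE)
  idx <- which(keep)
  rng <- GenomicAlignments::extractAlignmentRangesOnReference(
    cigar[idx], pos = rec$pos[idx])
  starts <- as.list(BiocGenerics::start(rng))
  ends <- as.list(BiocGenerics::end(rng))
  ops <- GenomicAlignments::explodeCigarOps(cigar[idx])
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar[idx])
  seqs <- allseq[idx]
  nsq <- nchar(seqs)
  strand <- as.character(rec$strand[idx])
  lead_s <- vapply(seq_along(idx), function(j)
    if (ops[[j]][1] == "S") lens[[j]][1] else 0L, 0L)
  trail_s <- vapply(seq_along(idx), function(j) {
    k <- length(ops[[j]])
    if (ops[[j]][k] == "S") lens[[j]][k] else 0L
  }, 0L)
  plus <- strand == "+"
  clip <- character(length(idx))
  clip[plus] <- substr(seqs[plus], nsq[plus] - trail_s[plus] + 1L, nsq[plus])
  minus_clip <- substr(seqs[!plus], 1L, lead_s[!plus])
  if (length(minus_clip))
    clip[!plus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(minus_clip)))
  clip[nchar(clip) < min_clip_report] <- ""
  ref_pos <- ifelse(plus,
                    vapply(ends, function(e) e[length(e)], 0L),
                    vapply(starts, function(s) s[1] - 1L, 0L))
  blocks <- Map(function(s, e) cbind(start = s - 1L, end = e), starts, ends)
  data.frame(
    read_id = rec$qname[idx],
    chrom = as.character(rec$rname[idx]),
    strand = strand,
    clip3_seq = clip,
    clip3_ref_pos = as.integer(ref_pos),
    blocks = I(unname(blocks)),
    stringsAsFactors = FALSE)
}

#' Read gene models from GTF
#'
#' Builds one model per `gene_id` from exon features.  The 3' UTR is taken
#' from `three_prime_utr`/`UTR` features when present, otherwise inferred as
#' the exonic region 3' of the last CDS base; genes without CDS have no 3'
#' UTR.  Coordinates are converted to 0-based half-open.
#'
#' @param path GTF file with exon (and optionally CDS/UTR) features.
#' @return An object of class `gene_models`: a list with data.frames `genes`
#'   (gene_id, chrom, strand, start, end, utr3_start, utr3_end, utr5_start,
#'   utr5_end; NA when absent) and `exons` (gene_id, start, end).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df$start0 <- df$start - 1L   # to 0-based half-open
  df$end0 <- df$end
  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) stop("GTF contains no exon features", call. = FALSE)
  genes <- list(); exons <- list()
  for (gid in unique(ex$gene_id)) {
    gdf <- df[df$gene_id == gid, , drop = FALSE]
    e <- gdf[gdf$type == "exon", , drop = FALSE]
    e <- e[order(e$start0), , drop = FALSE]
    strand <- as.character(e$strand[1]); chrom <- as.character(e$seqnames[1])
    span <- c(min(e$start0), max(e$end0))
    if (any(e$start0 < span[1] | e$end0 > span[2])) {
      warning("gene ", gid, " has exon outside span; rejected"); next
    }
    if (nrow(e) > 1 && any(e$start0[-1] < e$end0[-nrow(e)])) {
      warning("gene ", gid, " has overlapping exons; rejected"); next
    }
    utr3 <- c(NA_integer_, NA_integer_); utr5 <- c(NA_integer_, NA_integer_)
    u <- gdf[gdf$type %in% c("three_prime_utr", "3UTR"), , drop = FALSE]
    cds <- gdf[gdf$type == "CDS", , drop = FALSE]
    if (nrow(u) > 0L) {
      utr3 <- c(min(u$start0), max(u$end0))
    } else if (nrow(cds) > 0L) {
      if (strand == "+") {
        cend <- max(cds$end0)
        tail_bases <- e[e$end0 > cend, , drop = FALSE]
        if (nrow(tail_bases) > 0L)
          utr3 <- c(max(cend, min(tail_bases$start0)), max(tail_bases$end0))
      } else {
        cstart <- min(cds$start0)
        tail_bases <- e[e$start0 < cstart, , drop = FALSE]
        if (nrow(tail_bases) > 0L)
          utr3 <- c(min(tail_bases$start0), min(cstart, max(tail_bases$end0)))
      }
      if (!is.na(utr3[1]) && utr3[2] <= utr3[1]) utr3 <- c(NA_integer_, NA_integer_)
    }
    if (nrow(cds) > 0L) {
      if (strand == "+") {
        cstart <- min(cds$start0)
        head_bases <- e[e$start0 < cstart, , drop = FALSE]
        if (nrow(head_bases) > 0L)
          utr5 <- c(min(head_bases$start0), min(cstart, max(head_bases$end0)))
      } else {
        cend <- max(cds$end0)
        head_bases <- e[e$end0 > cend, , drop = FALSE]
        if (nrow(head_bases) > 0L)
          utr5 <- c(max(cend, min(head_bases$start0)), max(head_bases$end0))
      }
      if (!is.na(utr5[1]) && utr5[2] <= utr5[1]) utr5 <- c(NA_integer_, NA_integer_)
    }
    genes[[gid]] <- data.frame(
      gene_id = gid, chrom = chrom, strand = strand,
      start = span[1], end = span[2],
      utr3_start = utr3[1], utr3_end = utr3[2],
      utr5_start = utr5[1], utr5_end = utr5[2],
      stringsAsFactors = FALSE)
    exons[[gid]] <- data.frame(gene_id = gid, start = e$start0, end = e$end0,
                               stringsAsFactors = FALSE)
  }
  structure(list(genes = do.call(rbind, c(genes, list(make.row.names = FALSE))),
                 exons = do.call(rbind, c(exons, list(make.row.names = FALSE)))),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons\n")
  invisible(x)
}

# Internal GTF formatter shared by the simulator and write_gene_models so the
# round trip is byte-stable.  cds: optional data.frame(gene_id, start, end).
format_gtf <- function(genes, exons, cds = NULL, source = "polyacall") {
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    attr_g <- sprintf('gene_id "%s";', g$gene_id)
    lines <- c(lines, paste(g$chrom, source, "gene", g$start + 1L, g$end,
                            ".", g$strand, ".", attr_g, sep = "\t"))
    e <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    for (j in seq_len(nrow(e)))
      lines <- c(lines, paste(g$chrom, source, "exon", e$start[j] + 1L,
                              e$end[j], ".", g$strand, ".", attr_g, sep = "\t"))
    if (!is.null(cds)) {
      cc <- cds[cds$gene_id == g$gene_id, , drop = FALSE]
      cc <- cc[order(cc$start), , drop = FALSE]
      for (j in seq_len(nrow(cc)))
        lines <- c(lines, paste(g$chrom, source, "CDS", cc$start[j] + 1L,
                                cc$end[j], ".", g$strand, ".", attr_g,
                                sep = "\t"))
    }
  }
  lines
}

#' Write gene models to GTF
#'
#' Emits gene/exon records plus a CDS record per gene when a 3' UTR is
#' annotated, so that [read_gene_models()] recovers the same models.
#'
#' @param gm A `gene_models` object.
#' @param path Output GTF path.
#' @export
write_gene_models <- function(gm, path) {
  cds <- NULL
  has3 <- !is.na(gm$genes$utr3_start)
  if (any(has3)) {
    rows <- lapply(which(has3), function(i) {
      g <- gm$genes[i, ]
      e <- gm$exons[gm$exons$gene_id == g$gene_id, , drop = FALSE]
      if (g$strand == "+") {
        cs <- if (!is.na(g$utr5_end)) g$utr5_end else min(e$start)
        data.frame(gene_id = g$gene_id, start = cs, end = g$utr3_start,
                   stringsAsFactors = FALSE)
      } else {
        ce <- if (!is.na(g$utr5_start)) g$utr5_start else max(e$end)
        data.frame(gene_id = g$gene_id, start = g$utr3_end, end = ce,
                   stringsAsFactors = FALSE)
      }
    })
    cds <- do.call(rbind, rows)
  }
  writeLines(format_gtf(gm$genes, gm$exons, cds), path)
  invisible(path)
}

#' Read a PAS site table from BED6+1
#'
#' Dialect: chrom, start, end, name (`gene_id:site_index`), score (read
#' count), strand, column 7 = PAU.  Lines whose PAU falls outside \[0,1\]
#' are rejected with a warning.
#'
#' @param path BED file.
#' @return data.frame with columns chrom, start, end, name, read_count,
#'   strand, pau, gene_id (parsed from name).
#' @export
read_pas_bed <- function(path) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), read_count = integer(),
                      strand = character(), pau = numeric(),
                      gene_id = character(), stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(f, length, 0L) >= 7L
  f <- f[ok]
  if (length(f) == 0L) return(empty)
  pau <- as.numeric(vapply(f, `[[`, "", 7L))
  valid <- !is.na(pau) & pau >= 0 & pau <= 1
  if (any(!valid))
    warning(sum(!valid), " BED line(s) with PAU outside [0,1] rejected")
  f <- f[valid]; pau <- pau[valid]
  if (length(f) == 0L) return(empty)
  name <- vapply(f, `[[`, "", 4L)
  data.frame(
    chrom = vapply(f, `[[`, "", 1L),
    start = as.integer(vapply(f, `[[`, "", 2L)),
    end = as.integer(vapply(f, `[[`, "", 3L)),
    name = name,
    read_count = as.integer(round(as.numeric(vapply(f, `[[`, "", 5L)))),
    strand = vapply(f, `[[`, "", 6L),
    pau = pau,
    gene_id = sub(":[^:]*$", "", name),
    stringsAsFactors = FALSE)
}

#' Write a PAS site table to BED6+1
#'
#' @param sites data.frame as returned by [read_pas_bed()] or produced by the
#'   calling pipeline (needs chrom, start, end, name or gene_id, read_count,
#'   strand, pau).
#' @param path Output path.
#' @export
write_pas_bed <- function(sites, path) {
  if (nrow(sites) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  name <- if ("name" %in% names(sites) && !anyNA(sites$name)) sites$name else {
    idx <- stats::ave(seq_len(nrow(sites)), sites$gene_id, FUN = seq_along)
    paste0(sites$gene_id, ":", idx)
  }
  writeLines(paste(sites$chrom, sites$start, sites$end, name,
                   sites$read_count, sites$strand,
                   format_pau(sites$pau), sep = "\t"), path)
  invisible(path)
}

format_pau <- function(x) sub("0+$", "", sub("\\.$", ".0", sprintf("%.6f", x)))

#' Per-base read-end coverage from cleavage events
#'
#' @param events data.frame of cleavage events on a single chromosome and
#'   strand (columns chrom, strand, position).
#' @return A `coverage_track`: list(chrom, strand, offset, counts) where
#'   `counts[i]` is the number of events at position `offset + i - 1`.
#' @export
compute_end_coverage <- function(events) {
  if (nrow(events) == 0L)
    return(structure(list(chrom = NA_character_, strand = NA_character_,
                          offset = 0L, counts = integer(0)),
                     class = "coverage_track"))
  stopifnot(length(unique(events$chrom)) == 1L,
            length(unique(events$strand)) == 1L)
  off <- min(events$position)
  counts <- tabulate(events$position - off + 1L,
                     nbins = max(events$position) - off + 1L)
  structure(list(chrom = events$chrom[1], strand = events$strand[1],
                 offset = as.integer(off), counts = as.integer(counts)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track %s(%s): [%d, %d), %d read ends\n",
              x$chrom, x$strand, x$offset, x$offset + length(x$counts),
              sum(x$counts)))
  invisible(x)
}

#' Write a coverage track to bedGraph
#'
#' Zero-count runs are omitted; coordinates are 0-based half-open.
#' @param track A `coverage_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  nz <- which(track$counts > 0L)
  if (length(nz) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  r <- rle(track$counts)
  end <- cumsum(r$lengths); start <- end - r$lengths
  keep <- r$values > 0L
  writeLines(paste(track$chrom, track$offset + start[keep],
                   track$offset + end[keep], r$values[keep], sep = "\t"), path)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph file covering a single chromosome.
#' @param strand strand to attach to the track (bedGraph is unstranded).
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, strand = "+") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#)", lines)]
  if (length(lines) == 0L)
    return(structure(list(chrom = NA_character_, strand = strand,
                          offset = 0L, counts = integer(0)),
                     class = "coverage_track"))
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  chrom <- f[1, 1]
  start <- as.integer(f[, 2]); end <- as.integer(f[, 3])
  val <- as.integer(round(as.numeric(f[, 4])))
  off <- min(start)
  counts <- integer(max(end) - off)
  for (i in seq_along(start))
    counts[(start[i] - off + 1L):(end[i] - off)] <- val[i]
  structure(list(chrom = chrom, strand = strand, offset = off,
                 counts = counts), class = "coverage_track")
}
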