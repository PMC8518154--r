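# Classification of soft-clipped polyA tails and removal of internally
# primed (misprimed) reads.
#
# Tail rules (clip sequence in transcript orientation):
#   (a) clip length in [6, 20): A-fraction of the whole clip >= 0.95
#   (b) clip length >= 20: A-fraction of the first 20 nt >= 0.80 AND
#       A-fraction of nt 21..40 (or the remainder when shorter) >= 0.95
#
# Mispriming (flank windows on the transcript strand, excluding the cleavage
# base; upstream = transcript-5' side):
#   longread mode: >= min_a A's in the upstream window OR in the downstream
#                  window (counts, not runs)
#   3seq mode:     a run of >= min_a consecutive A's anywhere in the
#                  concatenated upstream+downstream window

#' Classify a soft-clipped segment as a polyA tail
#'
#' @param clip3_seq soft-clip sequence in transcript orientation (5'->3').
#' @param consecutive if `TRUE`, additionally require a run of at least six
#'   consecutive adenosines (run-based reading of the minimum-stretch rule);
#'   the default applies the composition thresholds only.
#' @return list with `has_tail` (logical), `tail_length` (clip length, nt)
#'   and `purity` (A fraction of the evaluated segment, at most 40 nt).
#' @export
classify_polya_tail <- function(clip3_seq, consecutive = FALSE) {
  check_nucleotides(clip3_seq, "soft clip")
  n <- nchar(clip3_seq)
  evaluated <- substr(clip3_seq, 1L, min(n, 40L))
  purity <- if (n == 0L) 0 else
    count_letter(evaluated, "A") / nchar(evaluated)
  has <- if (n < 20L) {
    n >= 6L && count_letter(clip3_seq, "A") / n >= 0.95
  } else {
    first20 <- substr(clip3_seq, 1L, 20L)
    rest <- substr(clip3_seq, 21L, min(n, 40L))
    ok1 <- count_letter(first20, "A") / 20 >= 0.80
    ok2 <- !nzchar(rest) || count_letter(rest, "A") / nchar(rest) >= 0.95
    ok1 && ok2
  }
  if (has && consecutive)
    has <- longest_run(evaluated, "A") >= 6L
  list(has_tail = isTRUE(has), tail_length = n, purity = purity)
}

# Flank windows around a cleavage position, on the transcript strand.
# Returns list(upstream, downstream) as transcript-oriented strings, windows
# truncated at chromosome ends; the cleavage base itself is excluded.
cleavage_flanks <- function(genome, chrom, strand, position, up, down) {
  if (strand == "+") {
    u <- genome_slice(genome, chrom, position - up, position)
    d <- genome_slice(genome, chrom, position + 1L, position + 1L + down)
  } else {
    u <- revcomp(genome_slice(genome, chrom, position + 1L, position + 1L + up))
    d <- revcomp(genome_slice(genome, chrom, position - down, position))
  }
  list(upstream = u, downstream = d)
}

#' Test a cleavage event for internal priming against the genome
#'
#' Scans the genomic flanks of the cleavage position on the transcript strand
#' for adenosine content.  In `longread` mode a read is misprimed when either
#' flank window contains at least `min_a` adenosines; in `3seq` mode when the
#' combined window contains a run of at least `min_a` consecutive adenosines.
#'
#' @param genome [Biostrings::DNAStringSet] reference genome.
#' @param chrom,strand,position cleavage event coordinates (`position` is the
#'   first reference base past the aligned 3' end, 0-based).
#' @param mode `"longread"` (default windows 10/10) or `"3seq"` (10/12).
#' @param up_window,down_window flank widths in nt; defaults depend on `mode`.
#' @param min_a adenosine threshold (count or run length by mode).
#' @return `TRUE` when the event is misprimed.
#' @export
filter_mispriming <- function(genome, chrom, strand, position,
                              mode = c("longread", "3seq"),
                              up_window = NULL, down_window = NULL,
                              min_a = 6L) {
  mode <- match.arg(mode)
  up <- up_window %||% 10L
  down <- down_window %||% (if (mode == "3seq") 12L else 10L)
  fl <- cleavage_flanks(genome, chrom, strand, position, up, down)
  if (mode == "longread") {
    count_letter(fl$upstream, "A") >= min_a ||
      count_letter(fl$downstream, "A") >= min_a
  } else {
    longest_run(paste0(fl$upstream, fl$downstream), "A") >= min_a
  }
}

#' Extract reliable cleavage events from parsed alignments
#'
#' In `longread` mode, reads whose 3' soft clip classifies as a polyA tail
#' and whose genomic flanks do not look internally primed yield one cleavage
#' event each.  In `3seq` mode every read 3' end is taken (no tail required)
#' and only the mispriming filter is applied.
#'
#' @param reads data.frame from [parse_alignments()].
#' @param genome [Biostrings::DNAStringSet] reference genome.
#' @param mode `"longread"` or `"3seq"`.
#' @param min_a,consecutive passed to the tail/mispriming rules.
#' @return data.frame of cleavage events: read_id, chrom, strand, position
#'   (0-based, first reference base past the aligned 3' end in transcript
#'   orientation), tail_length, purity, plus the read's aligned `blocks`
#'   list-column.
#' @export
extract_cleavage_events <- function(reads, genome,
                                    mode = c("longread", "3seq"),
                                    min_a = 6L, consecutive = FALSE) {
  mode <- match.arg(mode)
  genome <- as_genome_chars(genome)
  n <- nrow(reads)
  keep <- logical(n); tl <- integer(n); pur <- numeric(n); pos <- integer(n)
  for (i in seq_len(n)) {
    pos[i] <- if (reads$strand[i] == "+") reads$clip3_ref_pos[i]
              else reads$clip3_ref_pos[i] - 1L
    if (mode == "longread") {
      tc <- tryCatch(classify_polya_tail(reads$clip3_seq[i], consecutive),
                     error = function(e) {
                       warning("read ", reads$read_id[i], ": ",
                               conditionMessage(e))
                       list(has_tail = FALSE, tail_length = 0L, purity = 0)
                     })
      tl[i] <- tc$tail_length; pur[i] <- tc$purity
      if (!tc$has_tail) next
    }
    if (filter_mispriming(genome, reads$chrom[i], reads$strand[i], pos[i],
                          mode = mode, min_a = min_a)) next
    keep[i] <- TRUE
  }
  out <- data.frame(read_id = reads$read_id[keep],
                    chrom = reads$chrom[keep],
                    strand = reads$strand[keep],
                    position = pos[keep],
                    tail_length = tl[keep],
                    purity = pur[keep],
                    stringsAsFactors = FALSE)
  out$blocks <- reads$blocks[keep]
  out
}
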