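# Positional signal-site (hexamer) profiles and downstream GT-content
# checks around called cleavage sites, with one-sided Fisher enrichment
# tests.  Offsets are relative to the cleavage position in transcript
# orientation: negative = upstream (5'), positive = downstream.

PAS_SIGNAL_MOTIFS <- c("AATAAA", "ATTAAA", "AGTAAA", "TATAAA",
                       "CATAAA", "GATAAA")

# Transcript-oriented flank string spanning motif start offsets
# -flank..+flank; index offset o at position o + flank + 1.  Motifs of width
# w need w-1 extra bases on the 3' side.
site_flank <- function(genome, chrom, strand, cleavage_pos,
                       flank = 100L, extra = 5L) {
  if (strand == "+") {
    lo <- cleavage_pos - flank
    s <- genome_slice(genome, chrom, lo, cleavage_pos + flank + extra + 1L)
    pad_l <- max(0L, -lo)
  } else {
    hi <- cleavage_pos + flank
    s <- revcomp(genome_slice(genome, chrom, cleavage_pos - flank - extra,
                              hi + 1L))
    pad_l <- max(0L, hi + 1L - genome_seqlen(genome, chrom))
  }
  paste0(strrep("N", pad_l),
         s,
         strrep("N", 2L * flank + extra + 1L - pad_l - nchar(s)))
}

#' Positional motif occurrence profiles around cleavage sites
#'
#' For each site the ±`flank` nt flank (transcript strand) is scanned and
#' every offset where a motif starts is counted once (first-start
#' convention; overlapping occurrences at distinct offsets each count).
#'
#' @param sites PAS site table with chrom, strand and `cleavage_pos` (or an
#'   `end`/`start` pair in the window convention, from which the cleavage
#'   position is taken).
#' @param genome [Biostrings::DNAStringSet].
#' @param motifs character vector of 6-mers; default = the six signal-site
#'   hexamers plus the `AAAAAA` negative control.
#' @param flank half-width of the scanned flank in nt.
#' @return data.frame with columns motif, offset (-flank..flank) and count.
#' @export
positional_motif_profile <- function(sites, genome,
                                     motifs = c(PAS_SIGNAL_MOTIFS, "AAAAAA"),
                                     flank = 100L) {
  if (any(nchar(motifs) != 6L))
    stop("motifs must be 6-mers", call. = FALSE)
  genome <- as_genome_chars(genome)
  offsets <- seq.int(-flank, flank)
  prof <- matrix(0L, nrow = length(offsets), ncol = length(motifs),
                 dimnames = list(NULL, motifs))
  cp <- site_cleavage_pos(sites)
  for (i in seq_len(nrow(sites))) {
    fl <- site_flank(genome, sites$chrom[i], sites$strand[i], cp[i],
                     flank = flank, extra = 5L)
    for (m in motifs) {
      hits <- gregexpr(m, fl, fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      # gregexpr reports non-overlapping matches; rescan for all starts
      starts <- integer(0)
      from <- 1L
      while (TRUE) {
        h <- regexpr(m, substr(fl, from, nchar(fl)), fixed = TRUE)
        if (h == -1L) break
        starts <- c(starts, from + h - 1L)
        from <- from + h
      }
      off <- starts - flank - 1L
      off <- off[off >= -flank & off <= flank]
      prof[off + flank + 1L, m] <- prof[off + flank + 1L, m] + 1L
    }
  }
  data.frame(motif = rep(motifs, each = length(offsets)),
             offset = rep(offsets, length(motifs)),
             count = as.integer(prof),
             stringsAsFactors = FALSE)
}

site_cleavage_pos <- function(sites) {
  if ("cleavage_pos" %in% names(sites)) return(sites$cleavage_pos)
  ifelse(sites$strand == "+", sites$end, sites$start)
}

# Does the motif start anywhere in [win[1], win[2]] (offsets, inclusive)?
motif_in_window <- function(flank_seq, motif, win, flank) {
  lo <- win[1] + flank + 1L; hi <- win[2] + flank + 1L
  seg <- substr(flank_seq, lo, hi + nchar(motif) - 1L)
  grepl(motif, seg, fixed = TRUE)
}

#' One-sided Fisher enrichment of a motif near the cleavage site
#'
#' Compares the number of sites carrying the motif within `window` (offsets
#' relative to the cleavage position, upstream negative) against the same
#' count in a disjoint `control_window`.  The odds ratio is the
#' cross-product ratio with a Haldane 0.5 correction when any cell is zero;
#' the p-value is the one-sided (greater) Fisher exact test.
#'
#' @param sites,genome as in [positional_motif_profile()].
#' @param motif a 6-mer.
#' @param window,control_window length-2 integer vectors of inclusive offset
#'   bounds; defaults `c(-30, -20)` and its downstream mirror `c(20, 30)`.
#' @return list with `odds_ratio`, `p_value` and the 2x2 `table`
#'   (rows: window/control, cols: with/without motif).
#' @export
motif_enrichment_test <- function(sites, genome, motif = "AATAAA",
                                  window = c(-30L, -20L),
                                  control_window = c(20L, 30L)) {
  if (nrow(sites) == 0L) stop("empty site set", call. = FALSE)
  if (nchar(motif) != 6L) stop("motif must be a 6-mer", call. = FALSE)
  if (window[2] >= control_window[1] && control_window[2] >= window[1])
    stop("window and control_window must be disjoint", call. = FALSE)
  genome <- as_genome_chars(genome)
  flank <- max(abs(c(window, control_window))) + 10L
  cp <- site_cleavage_pos(sites)
  in_win <- in_ctl <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    fl <- site_flank(genome, sites$chrom[i], sites$strand[i], cp[i],
                     flank = flank, extra = 5L)
    in_win[i] <- motif_in_window(fl, motif, window, flank)
    in_ctl[i] <- motif_in_window(fl, motif, control_window, flank)
  }
  tab <- matrix(c(sum(in_win), sum(!in_win), sum(in_ctl), sum(!in_ctl)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("window", "control"), c("with", "without")))
  fisher_enrichment(tab)
}

# One-sided Fisher (greater) with cross-product OR; Haldane correction for
# zero cells.
fisher_enrichment <- function(tab) {
  t2 <- tab
  if (any(tab == 0L)) t2 <- tab + 0.5
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(odds_ratio = unname(or), p_value = p, table = tab)
}

#' Downstream G/T content and its enrichment over shuffled offsets
#'
#' Computes each site's G+T fraction in the downstream `window` and compares
#' the number of GT-rich sites (fraction > `gt_cut`) against the same
#' statistic computed at a random control offset drawn uniformly from
#' ±\[60, 100\] per site, by a one-sided Fisher test.  Sites whose window is
#' all N are excluded.
#'
#' @param sites,genome as in [positional_motif_profile()].
#' @param window inclusive downstream offset bounds, default `c(10, 30)`.
#' @param gt_cut dichotomization threshold on the G+T fraction.
#' @param seed RNG seed for the control offsets.
#' @return list with `gt_fraction` (per site), `mean_gt`, and the Fisher
#'   `odds_ratio` / `p_value` / `table` of the dichotomized comparison.
#' @export
downstream_gt_content <- function(sites, genome, window = c(10L, 30L),
                                  gt_cut = 0.6, seed = 1L) {
  if (nrow(sites) == 0L) stop("empty site set", call. = FALSE)
  genome <- as_genome_chars(genome)
  width <- window[2] - window[1] + 1L
  cp <- site_cleavage_pos(sites)
  set.seed(seed)
  ctl_off <- sample(c(-1L, 1L), nrow(sites), replace = TRUE) *
    sample(60:(100 - width + 1L), nrow(sites), replace = TRUE)
  gt <- gt_ctl <- rep(NA_real_, nrow(sites))
  flank <- 110L
  for (i in seq_len(nrow(sites))) {
    fl <- site_flank(genome, sites$chrom[i], sites$strand[i], cp[i],
                     flank = flank, extra = 0L)
    seg <- substr(fl, window[1] + flank + 1L, window[2] + flank + 1L)
    cseg <- substr(fl, ctl_off[i] + flank + 1L,
                   ctl_off[i] + width - 1L + flank + 1L)
    if (grepl("[ACGT]", seg)) gt[i] <- frac_letters(gsub("N", "", seg), c("G", "T"))
    if (grepl("[ACGT]", cseg)) gt_ctl[i] <- frac_letters(gsub("N", "", cseg), c("G", "T"))
  }
  ok <- !is.na(gt) & !is.na(gt_ctl)
  tab <- matrix(c(sum(gt[ok] > gt_cut), sum(gt[ok] <= gt_cut),
                  sum(gt_ctl[ok] > gt_cut), sum(gt_ctl[ok] <= gt_cut)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("downstream", "control"),
                                c("gt_rich", "other")))
  fe <- fisher_enrichment(tab)
  list(gt_fraction = gt, mean_gt = mean(gt, na.rm = TRUE),
       odds_ratio = fe$odds_ratio, p_value = fe$p_value, table = tab)
}
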