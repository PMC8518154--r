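# Cross-method comparison of PAS/PAU sets: one-to-one site matching by
# interval overlap, per-gene Sum|dPAU| error, ROC/AUC under fixed
# truth/false-positive usage definitions, proximal/distal shift fractions
# and a pooled two-proportion chi-square test.

#' Match two PAS site sets one-to-one by interval overlap
#'
#' Same-strand intersection; pairs are accepted greedily by decreasing
#' overlap (ties broken in favour of the 5'-most partner), so each site
#' appears in at most one match.  Unmatched sites are emitted with an absent
#' partner.
#'
#' @param set_a,set_b site data.frames (chrom, start, end, strand; rows are
#'   identified by index).
#' @param min_overlap minimum overlap in bp to accept a pair.
#' @return data.frame with columns `idx_a`, `idx_b` (NA when unmatched) and
#'   `overlap_bp`.
#' @export
match_sites <- function(set_a, set_b, min_overlap = 1L) {
  na <- nrow(set_a); nb <- nrow(set_b)
  pairs <- NULL
  if (na > 0L && nb > 0L) {
    lev <- union(set_a$chrom, set_b$chrom)
    gra <- GenomicRanges::GRanges(factor(set_a$chrom, levels = lev),
                                  IRanges::IRanges(set_a$start + 1L, set_a$end),
                                  strand = set_a$strand)
    grb <- GenomicRanges::GRanges(factor(set_b$chrom, levels = lev),
                                  IRanges::IRanges(set_b$start + 1L, set_b$end),
                                  strand = set_b$strand)
    ov <- GenomicRanges::findOverlaps(gra, grb, minoverlap = min_overlap)
    if (length(ov) > 0L) {
      qa <- S4Vectors::queryHits(ov); qb <- S4Vectors::subjectHits(ov)
      w <- pmin(set_a$end[qa], set_b$end[qb]) -
        pmax(set_a$start[qa], set_b$start[qb])
      # 5'-most partner key for tie-breaks (strand-aware transcript 5')
      five_b <- ifelse(set_b$strand[qb] == "+", set_b$start[qb], -set_b$end[qb])
      five_a <- ifelse(set_a$strand[qa] == "+", set_a$start[qa], -set_a$end[qa])
      o <- order(-w, five_b, five_a)
      used_a <- logical(na); used_b <- logical(nb)
      keep <- logical(length(o))
      for (k in o) {
        if (!used_a[qa[k]] && !used_b[qb[k]]) {
          used_a[qa[k]] <- TRUE; used_b[qb[k]] <- TRUE; keep[k] <- TRUE
        }
      }
      pairs <- data.frame(idx_a = qa[keep], idx_b = qb[keep],
                          overlap_bp = as.integer(w[keep]))
    }
  }
  if (is.null(pairs))
    pairs <- data.frame(idx_a = integer(0), idx_b = integer(0),
                        overlap_bp = integer(0))
  un_a <- setdiff(seq_len(na), pairs$idx_a)
  un_b <- setdiff(seq_len(nb), pairs$idx_b)
  rbind(pairs,
        data.frame(idx_a = un_a,
                   idx_b = rep(NA_integer_, length(un_a)),
                   overlap_bp = rep(0L, length(un_a))),
        data.frame(idx_a = rep(NA_integer_, length(un_b)),
                   idx_b = un_b,
                   overlap_bp = rep(0L, length(un_b))))
}

#' Per-gene usage discordance between two methods
#'
#' `Sum |dPAU|` over the gene's matched site pairs; unmatched sites
#' contribute their full usage (so two methods calling completely different
#' sites score the maximum of 2).
#'
#' @param table_a,table_b `pau_table`s (need chrom, start, end, strand,
#'   gene_id, pau).
#' @param gene_id gene to score; must be present in at least one table.
#' @param matched_only if `TRUE`, unmatched sites are ignored.
#' @return list with `gene_id` and `error` in \[0, 2\].
#' @export
pau_error <- function(table_a, table_b, gene_id, matched_only = FALSE) {
  a <- table_a[table_a$gene_id == gene_id, , drop = FALSE]
  b <- table_b[table_b$gene_id == gene_id, , drop = FALSE]
  if (nrow(a) == 0L && nrow(b) == 0L)
    stop("gene absent from both tables: ", gene_id, call. = FALSE)
  m <- match_sites(a, b)
  matched <- m[!is.na(m$idx_a) & !is.na(m$idx_b), , drop = FALSE]
  err <- sum(abs(a$pau[matched$idx_a] - b$pau[matched$idx_b]))
  if (!matched_only) {
    err <- err +
      sum(a$pau[setdiff(seq_len(nrow(a)), matched$idx_a)]) +
      sum(b$pau[setdiff(seq_len(nrow(b)), matched$idx_b)])
  }
  list(gene_id = gene_id, error = err)
}

#' ROC curve of a test PAS set against a reference set
#'
#' Truth positives are reference sites with PAU above `truth_min_pau`.  The
#' test method's usage threshold `t` is swept from 1 to 0:
#' TPR(t) = fraction of truth sites matched by a test site with PAU > t;
#' FPR(t) = test sites with PAU > max(t, 0.05) lacking a truth match,
#' as a fraction of all unmatched test sites with PAU > 0.05.
#'
#' @param truth,test `pau_table`s.
#' @param truth_min_pau usage definition of a true site (strict >).
#' @return list of class `roc_curve`: thresholds, tpr, fpr, auc (trapezoid,
#'   with (0,0) and (1,1) endpoints).
#' @export
roc_auc <- function(truth, test, truth_min_pau = 0.05) {
  if (nrow(truth) == 0L) stop("empty truth set", call. = FALSE)
  pos <- which(truth$pau > truth_min_pau)
  if (length(pos) == 0L) stop("no truth sites above truth_min_pau", call. = FALSE)
  m <- match_sites(truth, test)
  matched <- m[!is.na(m$idx_a) & !is.na(m$idx_b), , drop = FALSE]
  # test PAU attached to each truth positive (NA when unmatched)
  truth_match_pau <- rep(NA_real_, nrow(truth))
  truth_match_pau[matched$idx_a] <- test$pau[matched$idx_b]
  unmatched_b <- setdiff(seq_len(nrow(test)), matched$idx_b)
  fp_pau <- test$pau[unmatched_b]
  fp_denom <- sum(fp_pau > 0.05)
  thresholds <- sort(unique(c(0, test$pau, 1)), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t)
    mean(!is.na(truth_match_pau[pos]) & truth_match_pau[pos] > t), 0)
  fpr <- vapply(thresholds, function(t) {
    if (fp_denom == 0L) 0 else sum(fp_pau > max(t, 0.05)) / fp_denom
  }, 0)
  xs <- c(0, fpr, 1); ys <- c(0, tpr, 1)
  o <- order(xs, ys)
  auc <- sum(diff(xs[o]) * (ys[o][-1] + ys[o][-length(ys)]) / 2)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d thresholds, AUC = %.3f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Fraction of genes preferring the distal 3' UTR site in one method
#'
#' Restricts to genes present in both tables with at least two 3' UTR sites
#' whose proximal (5'-most) and distal (3'-most) cleavage positions are
#' separated by `min_separation` or more, then counts genes whose distal
#' usage is higher in `table_a` than in `table_b` (and vice versa).
#'
#' @param table_a,table_b `pau_table`s with `context` and `cleavage_pos`.
#' @param min_separation minimum proximal-to-distal distance in bp.
#' @return list with `frac_distal_a`, `frac_distal_b`, `n_genes` and the
#'   per-gene data.frame `genes`.
#' @export
proximal_distal_shift <- function(table_a, table_b, min_separation = 500L) {
  pick <- function(tab, gid) {
    s <- tab[tab$gene_id == gid & tab$context == "3UTR", , drop = FALSE]
    if (nrow(s) < 2L) return(NULL)
    tx <- if (s$strand[1] == "+") s$cleavage_pos else -s$cleavage_pos
    s[order(tx), , drop = FALSE]
  }
  shared <- intersect(unique(table_a$gene_id), unique(table_b$gene_id))
  rows <- list()
  for (gid in shared) {
    a <- pick(table_a, gid); b <- pick(table_b, gid)
    if (is.null(a) || is.null(b)) next
    sep <- abs(a$cleavage_pos[nrow(a)] - a$cleavage_pos[1])
    if (sep < min_separation) next
    da <- a$pau[nrow(a)]; db <- b$pau[nrow(b)]
    rows[[gid]] <- data.frame(gene_id = gid, distal_pau_a = da,
                              distal_pau_b = db, separation = sep,
                              stringsAsFactors = FALSE)
  }
  genes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), distal_pau_a = numeric(),
               distal_pau_b = numeric(), separation = integer())
  list(frac_distal_a = if (nrow(genes)) mean(genes$distal_pau_a - genes$distal_pau_b > 0) else NA_real_,
       frac_distal_b = if (nrow(genes)) mean(genes$distal_pau_b - genes$distal_pau_a > 0) else NA_real_,
       n_genes = nrow(genes), genes = genes)
}

#' Fraction of reference cleavage positions recovered by called site windows
#'
#' A position counts as recovered when a same-strand called window contains
#' it, with the window taken as the closed interval `[start, end]`: the
#' cleavage coordinate is by construction the exclusive end of a plus-strand
#' window, so closing the interval makes recovery symmetric across strands.
#'
#' @param positions data.frame with chrom, strand, position (cleavage
#'   coordinates, e.g. a simulation truth table).
#' @param sites called site data.frame (chrom, strand, start, end).
#' @return list with `recovered` (logical per position) and `fraction`.
#' @export
site_recovery <- function(positions, sites) {
  rec <- vapply(seq_len(nrow(positions)), function(i) {
    any(sites$chrom == positions$chrom[i] &
          sites$strand == positions$strand[i] &
          sites$start <= positions$position[i] &
          positions$position[i] <= sites$end)
  }, FALSE)
  list(recovered = rec,
       fraction = if (length(rec)) mean(rec) else NA_real_)
}

#' Two-proportion z test (pooled chi-square form)
#'
#' Pooled-proportion chi-square with one degree of freedom and no continuity
#' correction; degenerate pooled proportions (0 or 1) give chi-square 0 and
#' p 1.
#'
#' @param k1,n1,k2,n2 successes and totals of the two samples.
#' @return list with `chisq`, `p_value`, `p1`, `p2`.
#' @export
two_proportion_test <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  if (pp <= 0 || pp >= 1)
    return(list(chisq = 0, p_value = 1, p1 = p1, p2 = p2))
  chisq <- (p1 - p2)^2 / (pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(chisq = chisq, p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       p1 = p1, p2 = p2)
}
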