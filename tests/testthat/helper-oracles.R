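# Independent brute-force oracles used to check the package's operations.
# These deliberately re-derive each quantity by direct counting/enumeration
# and share no code with the implementation.

# Tail rule by direct counting on exploded characters.
brute_tail <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 20) {
    n >= 6 && sum(ch == "A") / n >= 0.95
  } else {
    first <- ch[1:20]
    ok1 <- sum(first == "A") / 20 >= 0.80
    if (n == 20) return(ok1)
    rest <- ch[21:min(n, 40)]
    ok1 && sum(rest == "A") / length(rest) >= 0.95
  }
}

# Mispriming count rule on explicit flank strings.
brute_misprime_count <- function(up, down, min_a = 6) {
  cnt <- function(x) sum(strsplit(x, "", fixed = TRUE)[[1]] == "A")
  cnt(up) >= min_a || cnt(down) >= min_a
}

# Longest A run by explicit scan.
brute_longest_a_run <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  best <- 0; cur <- 0
  for (c in ch) {
    cur <- if (c == "A") cur + 1 else 0
    best <- max(best, cur)
  }
  best
}

# One-sided (greater) Fisher exact p by explicit hypergeometric sums with
# choose(); table rows (a,b) / (c,d).
brute_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- choose(c1, ks) * choose(n - c1, r1 - ks) / choose(n, r1)
  sum(probs[ks >= a])
}

# ROC by explicit recomputation at every threshold, using only the matched
# pairs and raw counting.
brute_roc_auc <- function(truth, test, truth_min_pau = 0.05) {
  m <- polyacall::match_sites(truth, test)
  mm <- m[!is.na(m$idx_a) & !is.na(m$idx_b), , drop = FALSE]
  pos <- which(truth$pau > truth_min_pau)
  tm <- rep(NA_real_, nrow(truth)); tm[mm$idx_a] <- test$pau[mm$idx_b]
  fp <- test$pau[setdiff(seq_len(nrow(test)), mm$idx_b)]
  denom <- sum(fp > 0.05)
  th <- sort(unique(c(0, test$pau, 1)), decreasing = TRUE)
  tpr <- fpr <- numeric(length(th))
  for (i in seq_along(th)) {
    t <- th[i]
    tpr[i] <- sum(!is.na(tm[pos]) & tm[pos] > t) / length(pos)
    fpr[i] <- if (denom == 0) 0 else sum(fp > max(t, 0.05)) / denom
  }
  xs <- c(0, fpr, 1); ys <- c(0, tpr, 1)
  o <- order(xs, ys)
  sum(diff(xs[o]) * (ys[o][-1] + ys[o][-length(ys)]) / 2)
}

# Direct O(n*k) numeric convolution with the explicit kernel formula.
brute_ricker_convolve <- function(counts, sigma, hw) {
  n <- length(counts)
  out <- numeric(n)
  for (x in seq_len(n)) {
    acc <- 0
    for (k in -hw:hw) {
      i <- x - k
      if (i >= 1 && i <= n)
        acc <- acc + counts[i] * (k^2 / sigma^4 - 1 / sigma^2) *
          exp(-k^2 / (2 * sigma^2))
    }
    out[x] <- acc
  }
  out
}

# Random PAU table on one gene for symmetry/bounds properties.
random_pau_table <- function(n_sites, gene = "g", seed) {
  set.seed(seed)
  starts <- sort(sample.int(5000, n_sites)) * 10L
  w <- rgamma(n_sites, 1)
  data.frame(chrom = "chrT", start = starts, end = starts + 100L,
             strand = "+", gene_id = gene, pau = w / sum(w),
             cleavage_pos = starts + 100L, context = "3UTR",
             stringsAsFactors = FALSE)
}
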