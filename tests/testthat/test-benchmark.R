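# Cross-method benchmarking: matching, Sum|dPAU| error, ROC, shifts.

mk_sites <- function(starts, strand = "+", chrom = "chrT", pau = NULL,
                     gene = "g") {
  data.frame(chrom = chrom, start = as.integer(starts),
             end = as.integer(starts + 100L), strand = strand,
             gene_id = gene, pau = pau %||% rep(1 / length(starts),
                                                length(starts)),
             cleavage_pos = as.integer(starts + 100L),
             context = "3UTR", stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("site matching is one-to-one by maximal same-strand overlap", {
  a <- mk_sites(900)
  b <- mk_sites(950)
  m <- match_sites(a, b)
  expect_equal(m$overlap_bp[!is.na(m$idx_a) & !is.na(m$idx_b)], 50L)
  # identical sets -> everything matched
  a2 <- mk_sites(c(100, 300, 500))
  m2 <- match_sites(a2, a2)
  expect_equal(sum(!is.na(m2$idx_a) & !is.na(m2$idx_b)), 3L)
  # opposite strands never match
  m3 <- match_sites(mk_sites(900), mk_sites(900, strand = "-"))
  expect_equal(sum(!is.na(m3$idx_a) & !is.na(m3$idx_b)), 0L)
  expect_equal(nrow(m3), 2L)
})

test_that("matching is invariant to row order and coordinate translation", {
  set.seed(2)
  a <- mk_sites(sort(sample.int(3000, 10)) * 3)
  b <- mk_sites(sort(sample.int(3000, 12)) * 3)
  n_matched <- function(x, y) {
    m <- match_sites(x, y); sum(!is.na(m$idx_a) & !is.na(m$idx_b))
  }
  base <- n_matched(a, b)
  perm <- sample.int(nrow(a))
  expect_equal(n_matched(a[perm, ], b), base)
  shift <- function(s) { s$start <- s$start + 5000L; s$end <- s$end + 5000L; s }
  expect_equal(n_matched(shift(a), shift(b)), base)
})

test_that("gene usage error matches worked examples and is symmetric and bounded", {
  a <- mk_sites(c(1000, 2000), pau = c(0.6, 0.4))
  b <- mk_sites(c(1000, 2000), pau = c(0.5, 0.5))
  expect_equal(pau_error(a, b, "g")$error, 0.2)
  # completely different sites -> maximal discordance
  a2 <- mk_sites(1000, pau = 1.0)
  b2 <- mk_sites(5000, pau = 1.0)
  expect_equal(pau_error(a2, b2, "g")$error, 2.0)
  expect_equal(pau_error(a2, b2, "g", matched_only = TRUE)$error, 0)
  expect_equal(pau_error(a, a, "g")$error, 0)
  expect_error(pau_error(a, b, "absent"), "absent")
  # symmetry and bounds on random tables
  for (seed in 1:10) {
    ta <- random_pau_table(sample(2:6, 1), seed = seed)
    tb <- random_pau_table(sample(2:6, 1), seed = seed + 100)
    e1 <- pau_error(ta, tb, "g")$error
    e2 <- pau_error(tb, ta, "g")$error
    expect_equal(e1, e2, tolerance = 1e-12)
    expect_gte(e1, 0); expect_lte(e1, 2 + 1e-12)
  }
})

test_that("ROC equals brute-force threshold enumeration and is exact on identity", {
  truth <- mk_sites(c(1000, 3000, 5000), pau = c(0.5, 0.3, 0.2))
  r <- roc_auc(truth, truth)
  expect_equal(r$auc, 1.0)
  # test set on another chromosome -> no true positives
  off <- mk_sites(c(1000, 3000), chrom = "chrU", pau = c(0.6, 0.4))
  r2 <- roc_auc(truth, off)
  expect_true(all(r2$tpr == 0))
  expect_error(roc_auc(truth[0, ], truth), "empty")
  # noisy + spurious test sets against the oracle
  set.seed(6)
  for (rep in 1:10) {
    n <- sample(5:25, 1)
    tr <- random_pau_table(n, seed = rep)
    te <- tr
    te$pau <- pmin(pmax(te$pau + runif(n, -0.1, 0.1), 0.001), 1)
    spur <- random_pau_table(max(2, n %/% 5), seed = rep + 50)
    spur$start <- spur$start + 777777L; spur$end <- spur$end + 777777L
    te <- rbind(te, spur)
    got <- roc_auc(tr, te)
    expect_equal(got$auc, brute_roc_auc(tr, te), tolerance = 1e-12)
    expect_true(all(diff(got$tpr) >= -1e-12))
    expect_true(all(diff(got$fpr) >= -1e-12))
  }
})

test_that("distal-shift fractions obey the separation filter", {
  a <- mk_sites(c(1000, 1600), pau = c(0.2, 0.8))   # separation 600
  b <- mk_sites(c(1000, 1600), pau = c(0.7, 0.3))
  r <- proximal_distal_shift(a, b, min_separation = 500L)
  expect_equal(r$n_genes, 1L)
  expect_equal(r$frac_distal_a, 1)
  expect_equal(r$frac_distal_b, 0)
  # separation below the cutoff excludes the gene
  a2 <- mk_sites(c(1000, 1400), pau = c(0.2, 0.8))
  b2 <- mk_sites(c(1000, 1400), pau = c(0.7, 0.3))
  expect_equal(proximal_distal_shift(a2, b2, 500L)$n_genes, 0L)
})

test_that("planted distal shifts are recovered in aggregate", {
  set.seed(41)
  n <- 400; shifted <- runif(n) < 0.3
  rows_a <- rows_b <- list()
  for (i in seq_len(n)) {
    g <- sprintf("g%03d", i)
    base <- runif(1, 0.2, 0.6)
    da <- if (shifted[i]) min(base + 0.3, 0.95) else base
    pos <- c(1000L, 1600L) + 5000L * i
    rows_a[[i]] <- mk_sites(pos, pau = c(1 - da, da), gene = g)
    rows_b[[i]] <- mk_sites(pos, pau = c(1 - base, base), gene = g)
  }
  r <- proximal_distal_shift(do.call(rbind, rows_a), do.call(rbind, rows_b),
                             min_separation = 500L)
  expect_equal(r$n_genes, n)
  expect_lt(abs(r$frac_distal_a - 0.3), 0.05)
})

test_that("pooled two-proportion chi-square matches hand and prop.test values", {
  r <- two_proportion_test(30, 100, 10, 100)
  expect_equal(r$chisq, 12.5)
  expect_equal(r$p_value, pchisq(12.5, 1, lower.tail = FALSE))
  pt <- suppressWarnings(prop.test(c(30, 10), c(100, 100), correct = FALSE))
  expect_equal(r$chisq, unname(pt$statistic))
  expect_equal(two_proportion_test(10, 100, 10, 100)$chisq, 0)
  expect_equal(two_proportion_test(0, 10, 0, 10)$chisq, 0)
  expect_equal(two_proportion_test(0, 10, 0, 10)$p_value, 1)
})
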