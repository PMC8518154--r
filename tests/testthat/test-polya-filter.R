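# PolyA tail classification and mispriming filtering.

test_that("tail rule matches its worked examples and thresholds are inclusive", {
  expect_true(classify_polya_tail("AAAAAA")$has_tail)
  expect_false(classify_polya_tail("AAAAA")$has_tail)              # 5 < 6
  # 19 nt with 18 A: 0.947 < 0.95
  expect_false(classify_polya_tail(paste0(strrep("A", 18), "C"))$has_tail)
  # 40 nt: exactly 16/20 then 19/20 -> boundary inclusive
  s <- paste0(strrep("A", 16), "CCCC", strrep("A", 19), "G")
  expect_true(classify_polya_tail(s)$has_tail)
  # 15/20 in the first segment fails
  s2 <- paste0(strrep("A", 15), "CCCCC", strrep("A", 20))
  expect_false(classify_polya_tail(s2)$has_tail)
  expect_error(classify_polya_tail("AAAXAA"), "outside")
  tc <- classify_polya_tail(strrep("A", 30))
  expect_equal(tc$tail_length, 30L)
  expect_equal(tc$purity, 1)
})

test_that("tail rule agrees with brute force on all {A,C} strings of length <= 12", {
  for (len in 1:12) {
    grid <- expand.grid(rep(list(c("A", "C")), len), stringsAsFactors = FALSE)
    strs <- do.call(paste0, grid)
    got <- vapply(strs, function(s) classify_polya_tail(s)$has_tail, FALSE)
    want <- vapply(strs, brute_tail, FALSE)
    expect_identical(unname(got), unname(want))
  }
})

test_that("tail rule agrees with brute force on random long clips", {
  set.seed(21)
  for (i in 1:400) {
    len <- sample(13:45, 1)
    s <- paste(sample(c("A", "A", "A", "C", "G", "T"), len, TRUE),
               collapse = "")
    expect_identical(classify_polya_tail(s)$has_tail, brute_tail(s),
                     label = s)
  }
})

test_that("mispriming flank windows are counted on the transcript strand", {
  # plus strand: cleavage at 30; upstream [20,30), downstream [31,41)
  up <- "ACGTACGTAC"           # 3 A
  down <- "AAGAAAAAGC"         # 7 A -> misprimed
  g <- toy_genome(paste0(strrep("C", 20), up, "G", down, strrep("C", 20)))
  expect_true(filter_mispriming(g, "chrT", "+", 30L, mode = "longread"))
  g2 <- toy_genome(paste0(strrep("C", 20), up, "G", strrep("C", 30)))
  expect_false(filter_mispriming(g2, "chrT", "+", 30L, mode = "longread"))
  # minus strand: genomic T's read as A's on the transcript strand
  g3 <- toy_genome(paste0(strrep("C", 20), "GCTTTTTTTG", "G", strrep("C", 30)))
  # cleavage at 30 on '-': downstream window is genomic [20,30): 7 T -> 7 A
  expect_true(filter_mispriming(g3, "chrT", "-", 30L, mode = "longread"))
  expect_false(filter_mispriming(g3, "chrT", "+", 30L, mode = "longread"))
})

test_that("3'-Seq mode uses a run-based rule over the 22-nt combined window", {
  # run of 6 A split across the downstream window only
  down <- "CCAAAAAACCCC"       # contains a 6-run, but only 6 A of 12
  g <- toy_genome(paste0(strrep("C", 30), "G", down, strrep("C", 20)))
  expect_true(filter_mispriming(g, "chrT", "+", 30L, mode = "3seq"))
  # six scattered A's with max run 2: count rule would fire, run rule must not
  down2 <- "AACAACAACAAC"      # 8 A, max run 2
  g2 <- toy_genome(paste0(strrep("C", 30), "G", down2, strrep("C", 20)))
  expect_false(filter_mispriming(g2, "chrT", "+", 30L, mode = "3seq"))
  expect_true(filter_mispriming(g2, "chrT", "+", 30L, mode = "longread"))
})

test_that("mispriming count rule matches brute force on all A/C 10-mer flanks", {
  grid <- expand.grid(rep(list(c("A", "C")), 10), stringsAsFactors = FALSE)
  flanks <- do.call(paste0, grid)      # all 1024 A/C windows, 0-10 A's
  for (s in flanks) {
    g <- toy_genome(paste0(strrep("G", 10), "G", s, strrep("G", 10)))
    got <- filter_mispriming(g, "chrT", "+", 10L, mode = "longread")
    expect_identical(got, brute_misprime_count("GGGGGGGGGG", s),
                     label = s)
  }
})

test_that("cleavage events carry tail evidence and respect the filters end to end", {
  fx <- small_fixture()
  ev <- fx$events
  tr <- fx$reads[match(ev$read_id, fx$reads$read_id), ]
  # no misprimed or tail-less read survives
  expect_false(any(tr$true_class %in% c("misprime", "notail")))
  # emitted events sit exactly at the planted cleavage positions
  pas <- fx$ref$truth$pas
  key <- paste(pas$gene_id, pas$site_index)
  planted <- pas$position[match(paste(tr$true_gene, tr$true_site), key)]
  expect_equal(ev$position, planted)
  # post-hoc oracle scan: no emitted event violates the mispriming rule
  gchar <- as.character(fx$ref$genome)
  viol <- vapply(seq_len(nrow(ev)), function(i) {
    p <- ev$position[i]
    if (ev$strand[i] == "+") {
      up <- substr(gchar, p - 9, p); down <- substr(gchar, p + 2, p + 11)
    } else {
      rc <- function(x) chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]),
                                                     collapse = ""))
      up <- rc(substr(gchar, p + 2, p + 11)); down <- rc(substr(gchar, p - 9, p))
    }
    brute_misprime_count(up, down)
  }, FALSE)
  expect_equal(sum(viol), 0L)
})

test_that("all-tail-less input yields no events and clean single reads yield one", {
  fx <- small_fixture()
  g <- fx$ref$genome
  no_tail <- fx$alignments
  no_tail$clip3_seq <- ""
  expect_equal(nrow(extract_cleavage_events(no_tail, g)), 0L)
  tail_ids <- fx$reads$read_id[fx$reads$true_class == "tail"]
  one <- fx$alignments[match(tail_ids[1], fx$alignments$read_id), , drop = FALSE]
  one$clip3_seq <- strrep("A", 15)
  ev1 <- extract_cleavage_events(one, g)
  expect_equal(nrow(ev1), 1L)
  expect_equal(ev1$position,
               if (one$strand == "+") one$clip3_ref_pos
               else one$clip3_ref_pos - 1L)
})

test_that("lowering min_a never increases the number of emitted events", {
  fx <- small_fixture()
  n_by_min_a <- vapply(c(4L, 6L, 8L), function(m)
    nrow(extract_cleavage_events(fx$alignments, fx$ref$genome, min_a = m)), 0L)
  expect_true(all(diff(n_by_min_a) >= 0))
})
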