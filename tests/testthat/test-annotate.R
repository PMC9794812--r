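test_that("motif matching follows IUPAC degeneracy around the site", {
  # plus-strand context ...C A T G... matches VATB (V=C, B=G);
  # ...T A A G... fails (V excludes T, and the T of VATB mismatches)
  g <- make_genome(c(c1 = paste0(strrep("G", 10), "CATG",
                                 strrep("G", 6), "TAAG", strrep("G", 10))))
  calls <- data.frame(contig = "c1", pos = c(11L, 21L), strand = "+",
                      base = "A", k = 5L, n = 10L, p_raw = 0, p_adj = 0,
                      passed = TRUE)
  ms <- motif_summary(calls, g, list(rule_vatb()), flank = 3)
  expect_equal(unname(ms$fraction_matching["VATB"]), 0.5)
  expect_equal(ms$match_matrix[, "VATB"], c(TRUE, FALSE))
  # the centre column of the base-frequency matrix is all A
  expect_equal(unname(ms$base_freq["A", "0"]), 1)
  expect_equal(unname(colSums(ms$base_freq)), rep(1, 7), tolerance = 1e-9)
})

test_that("minus-strand flanks are reverse-complemented before matching", {
  # minus-strand GATC adenine: plus strand reads GATC at 10..13, minus A
  # is at position 12
  g <- make_genome(c(c1 = paste0(strrep("C", 10), "GATC", strrep("C", 10))))
  calls <- data.frame(contig = "c1", pos = 12L, strand = "-", base = "A",
                      k = 5L, n = 10L, p_raw = 0, p_adj = 0, passed = TRUE)
  ms <- motif_summary(calls, g, list(rule_gatc()), flank = 2)
  expect_equal(unname(ms$fraction_matching["GATC"]), 1)
})

test_that("sites too close to the contig edge are excluded and counted", {
  g <- make_genome(c(c1 = strrep("A", 30)))
  calls <- data.frame(contig = "c1", pos = c(1L, 15L), strand = "+",
                      base = "A", k = 1L, n = 1L, p_raw = 0, p_adj = 0,
                      passed = TRUE)
  ms <- motif_summary(calls, g, list(rule_gatc()), flank = 5)
  expect_equal(ms$total_sites, 1)
  expect_equal(ms$excluded_edge, 1)
})

test_that("symmetry statuses partition duplex occurrences", {
  g <- make_genome(c(c1 = paste0("AAAA", "GATC", "AAAA", "GATC",
                                 "AAAA", "GATC", "AAAA")))
  # occurrences at 4, 12, 20: plus A at s+1, minus A at s+2
  calls <- data.frame(
    contig = "c1",
    pos = c(5L, 6L, 13L),
    strand = c("+", "-", "+"),
    base = "A", k = 5L, n = 10L, p_raw = 0, p_adj = 0, passed = TRUE
  )
  sym <- classify_symmetry(calls, g, rule_gatc())
  expect_equal(nrow(sym), 3)
  expect_equal(sym$status[sym$start == 4], "full")
  expect_equal(sym$status[sym$start == 12], "hemi_plus")
  expect_equal(sym$status[sym$start == 20], "unmethylated")
  # VATB is degenerate-palindromic, so use a genuinely asymmetric rule
  expect_error(classify_symmetry(calls, g, motif_rule("AC", "AC", 0L)),
               "palindromic")
})

test_that("TSS distances are strand-oriented and nearest-assigned", {
  tss <- data.frame(contig = "c1", pos = c(1000L, 9000L),
                    strand = c("+", "-"))
  calls <- data.frame(contig = "c1",
                      pos = c(1000L, 1100L, 900L, 9100L, 8900L),
                      strand = "+", base = "A", k = 1L, n = 1L,
                      p_raw = 0, p_adj = 0, passed = TRUE)
  pr <- tss_profile(calls, tss, window = 500)
  # downstream of transcription is positive: +100 for the plus TSS,
  # and genomically-left of a minus TSS is downstream
  expect_equal(pr$distances, c(0L, 100L, -100L, -100L, 100L))
  expect_error(tss_profile(calls, tss[0, ], window = 500), "empty")
})

test_that("a planted 130-bp spacing is recovered as the dominant period", {
  tss <- data.frame(contig = "c1",
                    pos = seq(5000L, by = 5000L, length.out = 200),
                    strand = rep(c("+", "-"), 100))
  sites <- do.call(rbind, lapply(seq_len(nrow(tss)), function(i) {
    off <- 130L * (1:10)
    p <- if (tss$strand[i] == "+") tss$pos[i] + off else tss$pos[i] - off
    data.frame(contig = "c1", pos = p, strand = "+")
  }))
  pr <- tss_profile(sites, tss, window = 2000)
  expect_lte(abs(pr$dominant_period - 130), 5)
  expect_gt(pr$period_score, 0.5)
})

test_that("site-set overlaps report exact-match intersections and Jaccard", {
  a <- data.frame(contig = "c1", pos = 1:10, strand = "+")
  b <- data.frame(contig = "c1", pos = 6:15, strand = "+")
  ov <- overlap_sites(a, b)
  expect_equal(ov$n_both, 5)
  expect_equal(ov$jaccard, 5 / 15)
  expect_equal(overlap_sites(a, a)$jaccard, 1)
  d <- data.frame(contig = "c1", pos = 1:10, strand = "-")
  expect_equal(overlap_sites(a, d)$jaccard, 0)
  # symmetric in its arguments
  expect_equal(overlap_sites(b, a)$n_both, ov$n_both)
  expect_equal(overlap_sites(b, a)$jaccard, ov$jaccard)
})

test_that("region membership is half-open", {
  regions <- data.frame(contig = "c1", start = 100L, end = 200L)
  calls <- data.frame(contig = "c1", pos = c(150L, 200L, 100L),
                      strand = "+")
  sr <- sites_in_regions(calls, regions)
  expect_equal(sr$n_inside, 2)   # 150 and 100 in, 200 out
  expect_equal(sr$fraction, 2 / 3)
})
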