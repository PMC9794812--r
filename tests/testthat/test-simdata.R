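test_that("simulated genomes are deterministic and hit the target GC", {
  g1 <- simulate_genome(1, 1000, 0.5, seed = 7)
  g2 <- simulate_genome(1, 1000, 0.5, seed = 7)
  expect_identical(as.character(g1), as.character(g2))
  expect_false(identical(as.character(g1),
                         as.character(simulate_genome(1, 1000, 0.5, seed = 8))))

  g <- simulate_genome(1, 10000, 0.64, seed = 1)
  gc <- sum(Biostrings::letterFrequency(g, c("G", "C"))) / 10000
  expect_lt(abs(gc - 0.64), 0.03)

  g2c <- simulate_genome(2, 100, 0.5, seed = 1)
  expect_length(g2c, 2)
  expect_false(anyDuplicated(names(g2c)) > 0)

  expect_error(simulate_genome(1, 0, 0.5, 1), "length")
  expect_error(simulate_genome(1, 100, 1.2, 1), "gc")
})

test_that("plant_methylation covers all motif adenines at fraction 1", {
  g <- simulate_genome(1, 5000, 0.5, seed = 3)
  truth <- plant_methylation(g, rule_gatc(), 1.0, seed = 1)
  chars <- strsplit(as.character(g[[1]]), "")[[1]]
  # every site is an A on its strand
  plus <- truth[truth$strand == "+", ]
  minus <- truth[truth$strand == "-", ]
  expect_true(all(chars[plus$pos + 1] == "A"))
  expect_true(all(chars[minus$pos + 1] == "T"))
  # plus and minus adenines pair up per duplex occurrence (offset +1)
  expect_setequal(minus$pos, plus$pos + 1)
  # every genomic GATC is represented
  n_gatc <- length(gregexpr("GATC", as.character(g[[1]]))[[1]])
  expect_equal(nrow(plus), n_gatc)
})

test_that("plant_methylation subsamples occurrences at the stated fraction", {
  g <- simulate_genome(1, 10000, 0.5, seed = 4)
  all_sites <- plant_methylation(g, rule_gatc(), 1.0, seed = 1)
  half <- plant_methylation(g, rule_gatc(), 0.5, seed = 2)
  expect_lt(abs(nrow(half) / nrow(all_sites) - 0.5), 0.1)
  # joint inclusion: both strand adenines of an occurrence together
  hp <- half[half$strand == "+", ]
  hm <- half[half$strand == "-", ]
  expect_setequal(hm$pos, hp$pos + 1)
  expect_equal(nrow(plant_methylation(g, rule_gatc(), 0.0, seed = 1)), 0)
})

test_that("motif rules validate their pattern", {
  expect_error(motif_rule("bad", "GTTC", 1), "methyl_offset")
  expect_error(motif_rule("bad", "GAAC", 1), "exactly one")
  expect_error(motif_rule("bad", "GAXC", 1), "IUPAC")
  r <- rule_vatb()
  expect_identical(r$pattern, "VATB")
  expect_identical(r$methyl_offset, 1L)
})

test_that("endonuclease cleavage of the synthetic duplex yields 25 + 34 nt", {
  d <- synthetic_duplex(length = 59, methyl_pos = 25)
  cfg <- sim_config(1, capture_prob = 1, frag_len_mean = 59,
                    frag_len_sd = 0, seed = 5)
  a <- simulate_fragments_endo(d$genome, d$truth, cfg)
  expect_equal(nrow(a), 2)
  expect_setequal(a$end - a$start, c(25L, 34L))
  # the two pieces abut at the cut immediately 3' of the methylated A
  expect_equal(sort(c(a$start, a$end)), c(0L, 25L, 25L, 59L))
  # offset shifts the cut
  cfg2 <- sim_config(1, capture_prob = 1, frag_len_mean = 59,
                     frag_len_sd = 0, endo_cut_offset = 3L, seed = 5)
  a2 <- simulate_fragments_endo(d$genome, d$truth, cfg2)
  expect_setequal(a2$end - a2$start, c(28L, 31L))
})

test_that("every endo cut partitions the original fragment span", {
  g <- simulate_genome(1, 20000, 0.5, seed = 6)
  truth <- plant_methylation(g, rule_gatc(), 1.0, seed = 7)
  cfg <- sim_config(2000, capture_prob = 0.7, frag_len_mean = 300,
                    frag_len_sd = 80, seed = 8)
  a <- simulate_fragments_endo(g, truth, cfg)
  expect_gt(nrow(a), 2000)  # some fragments were cut
  # piece spans tile contiguous runs: total bases equal for cut pieces
  # vs an uncut rerun with capture 0
  cfg0 <- sim_config(2000, capture_prob = 0, frag_len_mean = 300,
                     frag_len_sd = 80, seed = 8)
  a0 <- simulate_fragments_endo(g, truth, cfg0)
  expect_equal(nrow(a0), 2000)
  expect_equal(sum(a$end - a$start), sum(a0$end - a0$start))
  expect_true(all(a$start < a$end))
})

test_that("capture probability controls the fraction of cut fragments", {
  # one contig where every fragment covers the single 6mA
  d <- synthetic_duplex(length = 100, methyl_pos = 50, seed = 2)
  cfg <- sim_config(100, capture_prob = 0.5, frag_len_mean = 100,
                    frag_len_sd = 0, seed = 9)
  a <- simulate_fragments_endo(d$genome, d$truth, cfg)
  n_cut <- nrow(a) - 100  # each cut adds one record
  expect_gt(n_cut, 50 - 15)
  expect_lt(n_cut, 50 + 15)
})

test_that("exonuclease stops leave the methylated A as the 5'-terminal base", {
  d <- synthetic_duplex(length = 59, methyl_pos = 25)
  cfg <- sim_config(1, capture_prob = 1, frag_len_mean = 59,
                    frag_len_sd = 0, seed = 5)
  a <- simulate_fragments_exo(d$genome, d$truth, cfg)
  plus <- a[a$strand == "+", ]
  expect_equal(plus$start, 24L)         # 1-based 25
  expect_equal(plus$end - plus$start, 35L)
  expect_equal(strand_5prime_base(plus, d$genome), "A")
  # the minus strand of a hemi-methylated duplex is never trimmed
  minus <- a[a$strand == "-", ]
  expect_equal(minus$start, 0L)
  expect_equal(minus$end, 59L)
  expect_identical(minus$source_tag, "shear")
})

test_that("all stop-derived 5' termini are adenines; bias grows with capture", {
  g <- simulate_genome(1, 30000, 0.5, seed = 10)
  truth <- plant_methylation(g, rule_gatc(), 1.0, seed = 11)
  afrac <- vapply(c(0, 0.3, 0.9), function(cp) {
    a <- simulate_fragments_exo(g, truth,
                                sim_config(3000, capture_prob = cp, seed = 12))
    stops <- a[a$source_tag == "exo_stop", ]
    if (nrow(stops) > 0)
      expect_true(all(strand_5prime_base(stops, g) == "A"))
    mean(strand_5prime_base(a, g) == "A")
  }, numeric(1))
  expect_true(all(diff(afrac) > 0))
})

test_that("WGA output is pure shear and matches endo with empty truth", {
  g <- simulate_genome(1, 10000, 0.5, seed = 13)
  cfg <- sim_config(500, seed = 14)
  w <- simulate_wga(g, cfg)
  expect_true(all(w$source_tag == "wga"))
  e <- simulate_fragments_endo(g, plant_methylation(g, rule_gatc(), 0, 1), cfg)
  expect_identical(w[c("contig", "start", "end", "strand")],
                   e[c("contig", "start", "end", "strand")])
})

test_that("WGA terminal positions are uniform away from contig ends", {
  g <- simulate_genome(1, 100000, 0.5, seed = 15)
  w <- simulate_wga(g, sim_config(50000, seed = 16))
  p5 <- ifelse(w$strand == "+", w$start, w$end - 1L)
  interior <- p5[p5 >= 1000 & p5 < 99000]
  bins <- cut(interior, breaks = seq(1000, 99000, by = 1000))
  gof <- suppressWarnings(chisq.test(table(bins)))
  expect_gt(gof$p.value, 0.001)
})

test_that("spike-in mixing is exactly invertible", {
  g <- simulate_genome(1, 5000, 0.5, seed = 17)
  host <- simulate_wga(g, sim_config(2000, seed = 18))
  spike <- simulate_wga(g, sim_config(100, seed = 19))
  mixed <- mix_spikein(host, spike, "host_", "spike_")
  expect_equal(nrow(mixed), 2100)
  expect_setequal(unique(mixed$contig), c("host_contig1", "spike_contig1"))
  parts <- partition_by_namespace(mixed, "spike_", host_prefix = "host_")
  expect_identical(parts$host, host)
  expect_identical(parts$spike, spike)
  expect_error(mix_spikein(host, spike, "s_", "s_"), "collision")
  # empty spike prefix matches nothing
  all_host <- partition_by_namespace(mixed, "")
  expect_equal(nrow(all_host$spike), 0)
  expect_equal(nrow(all_host$host), 2100)
  # unprefixed contigs are reported
  expect_error(partition_by_namespace(mixed, "spike_", host_prefix = "x_"),
               "neither prefix")
})

test_that("fragment simulators are deterministic under a fixed seed", {
  g <- simulate_genome(1, 20000, 0.5, seed = 20)
  truth <- plant_methylation(g, rule_gatc(), 1.0, seed = 21)
  cfg <- sim_config(1000, capture_prob = 0.4, seed = 22)
  expect_identical(simulate_fragments_endo(g, truth, cfg),
                   simulate_fragments_endo(g, truth, cfg))
  expect_identical(simulate_fragments_exo(g, truth, cfg),
                   simulate_fragments_exo(g, truth, cfg))
})
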