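test_that("the worked glutamine-repeat peptide is scanned correctly", {
  aars <- detect_aars("QQQQQSTWQQQQAAE")
  expect_equal(nrow(aars), 2L)
  expect_equal(aars$residue, c("Q", "Q"))
  expect_equal(aars$start, c(0L, 8L))
  expect_equal(aars$end, c(5L, 12L))
  expect_equal(sum(aars$length), 9L)
  expect_equal(compute_rrpk(15, aars), 600)
})

test_that("runs below the threshold, and runs of ambiguous residues, are not reported", {
  expect_equal(nrow(detect_aars("ACDEFGH")), 0L)
  expect_equal(nrow(detect_aars("AAAXAAA")), 0L)
  expect_equal(nrow(detect_aars("XXXXXX")), 0L)
  a <- detect_aars("AAAA")
  expect_equal(a$start, 0L)
  expect_equal(a$end, 4L)
  # min_len is configurable
  expect_equal(nrow(detect_aars("QQQ", min_len = 3L)), 1L)
  expect_error(detect_aars(""), "empty")
})

test_that("detected repeats match the brute-force maximal-run oracle", {
  set.seed(101)
  for (i in 1:80) {
    n <- sample(50:300, 1L)
    s <- if (i %% 2L == 0L) repeat_enriched_protein(n) else
      random_protein(n, alphabet = c(STANDARD_AA, "X"))
    got <- detect_aars(s)
    want <- oracle_detect_runs(s)
    expect_equal(got[c("residue", "start", "end")], want,
                 ignore_attr = TRUE)
  }
})

test_that("RRPK is bounded and reaches its extremes only at the degenerate cases", {
  expect_equal(compute_rrpk(100, detect_aars("ACDEF")), 0)
  full <- detect_aars("AAAA")
  expect_equal(compute_rrpk(4, full), 1000)
  expect_error(compute_rrpk(0, full), "positive")
  set.seed(7)
  for (i in 1:50) {
    s <- repeat_enriched_protein(sample(20:120, 1L))
    r <- compute_rrpk(nchar(s), detect_aars(s))
    expect_gte(r, 0); expect_lte(r, 1000)
  }
})

test_that("GC content excludes ambiguity codes and respects strand symmetries", {
  expect_equal(gc_content(c("GCGC", "ATAT", "ATGCN")), c(1, 0, 0.5))
  expect_true(is.na(gc_content("NNNN")))
  expect_error(gc_content(""), "empty")
  set.seed(11)
  for (i in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T", "N", "R"), 60, TRUE), collapse = "")
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    comp_s <- chartr("ACGT", "TGCA", s)
    expect_equal(gc_content(s), gc_content(rev_s))
    expect_equal(gc_content(s), gc_content(comp_s))
  }
})

test_that("protein thirds partition the sequence N-terminus first and conserve repeat residues", {
  expect_equal(aarscan:::region_boundaries(15L), c(0L, 5L, 10L, 15L))
  expect_equal(aarscan:::region_boundaries(16L), c(0L, 6L, 11L, 16L))
  expect_equal(aarscan:::region_boundaries(17L), c(0L, 6L, 12L, 17L))
  s <- "QQQQQSTWQQQQAAE"
  rp <- regional_profile(s, detect_aars(s))
  expect_equal(rp$rrpk_1, 1000)
  expect_equal(rp$rrpk_2, 400)
  expect_equal(rp$rrpk_3, 400)
  # no-repeat protein
  rp0 <- regional_profile("ACDEFGHIK", detect_aars("ACDEF"))
  expect_equal(unlist(rp0[1:3]), c(rrpk_1 = 0, rrpk_2 = 0, rrpk_3 = 0))
  # conservation identity: sum over regions of len * rrpk / 1000 = repeat total
  set.seed(23)
  for (i in 1:40) {
    s <- repeat_enriched_protein(sample(10:200, 1L))
    a <- detect_aars(s)
    rp <- regional_profile(s, a)
    tot <- sum(unlist(rp[paste0("len_", 1:3)]) *
                 unlist(rp[paste0("rrpk_", 1:3)])) / 1000
    expect_equal(tot, sum(a$length))
  }
})

test_that("regional GC is computed over the codons projected into each region", {
  # 6 residues: first third gets codons 1-2, etc.
  cds <- paste0("GGGGGG", "ATAATA", "GCGCAT")
  rp <- regional_profile("GGIIAH", detect_aars("ACDEF"), cds = cds)
  expect_equal(rp$gc_1, 1)
  expect_equal(rp$gc_2, 0)
  expect_equal(rp$gc_3, 4 / 6)
})

test_that("repeat and background residue compositions tally correctly and sum to one", {
  prot <- data.frame(id = "p1", sequence = "AAAACCCC", stringsAsFactors = FALSE)
  comp <- aar_residue_composition(detect_aars("AAAACCCC", protein_id = "p1"), prot)
  expect_equal(comp$repeat_fraction[comp$residue == "A"], 0.5)
  expect_equal(comp$repeat_fraction[comp$residue == "C"], 0.5)
  expect_equal(comp$background_fraction[comp$residue == "A"], 0.5)

  prot2 <- data.frame(id = "p2", sequence = "AAAAWY", stringsAsFactors = FALSE)
  comp2 <- aar_residue_composition(detect_aars("AAAAWY", protein_id = "p2"), prot2)
  expect_equal(comp2$repeat_fraction[comp2$residue == "A"], 1)
  expect_equal(comp2$background_fraction[comp2$residue == "A"], 4 / 6)

  # sums to 1 on a random proteome; repeat tally equals direct recount
  set.seed(5)
  prots <- data.frame(id = paste0("p", 1:20),
                      sequence = replicate(20, repeat_enriched_protein(150)),
                      stringsAsFactors = FALSE)
  sc <- scan_proteins(prots)
  comp3 <- aar_residue_composition(sc$aars, prots)
  expect_equal(sum(comp3$repeat_fraction), 1, tolerance = 1e-9)
  expect_equal(sum(comp3$background_fraction), 1, tolerance = 1e-9)
  direct <- unlist(lapply(seq_len(nrow(sc$aars)), function(i)
    rep(sc$aars$residue[i], sc$aars$length[i])))
  tally <- table(factor(direct, levels = comp3$residue))
  expect_equal(comp3$repeat_fraction, as.numeric(tally) / sum(tally))
  # no repeats anywhere -> flagged NA
  none <- aar_residue_composition(detect_aars("ACDEF"),
                                  data.frame(id = "q", sequence = "ACDEF"))
  expect_true(all(is.na(none$repeat_fraction)))
})

test_that("alanine, glycine and proline repeats are the GC-rich-codon class", {
  expect_true(all(classify_gc_rich(c("A", "G", "P"))))
  expect_false(any(classify_gc_rich(c("Q", "W", "S", "E"))))
})

test_that("species summaries average per-protein RRPK and count repeats per protein", {
  prots <- data.frame(id = c("a", "b", "c"),
                      species = c("s1", "s1", "s2"),
                      sequence = c("QQQQQSTWQQQQAAE", strrep("ACDE", 10), "AAAA"),
                      stringsAsFactors = FALSE)
  sc <- scan_proteins(prots)
  ss <- species_summary(sc$profiles)
  expect_equal(ss$mean_rrpk[ss$species == "s1"], (600 + 0) / 2)
  expect_equal(ss$aars_per_protein[ss$species == "s1"], 1)
  expect_equal(ss$mean_rrpk[ss$species == "s2"], 1000)
  expect_equal(ss$rcp_fraction, c(0.5, 1))
})
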