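test_that("ortholog groups validate widths, translation and codon gap placement", {
  g <- toy_group(c(p1 = "QQQQ--AA", p2 = "QQQQWWAA"))
  expect_equal(g$width, 8L)
  expect_equal(g$sequences[["p1"]], "QQQQAA")
  # codon alignment is 3x wide, gaps codon-sized and co-located
  expect_equal(nchar(g$codon_msa[["p1"]]), 24L)
  expect_equal(substr(g$codon_msa[["p1"]], 13, 18), "------")
  # ungapping any row reproduces the stored sequence
  expect_equal(gsub("-", "", g$msa[["p1"]]), g$sequences[["p1"]])
  expect_error(toy_group(c(p1 = "QQQQ", p2 = "QQQQQ")), "unequal")
  # a CDS that does not translate to the row is rejected
  expect_error(
    ortholog_group("bad",
                   data.frame(id = "p1", species = "s1"),
                   c(p1 = "QQ"), c(p1 = "CAACAT")),
    "translate")
})

test_that("repeats map to minimal alignment-column spans across gaps", {
  g <- toy_group(c(p1 = "QQQQ--AA", p2 = "QQQQWWAA"))
  aar <- detect_aars(g$sequences[["p1"]], protein_id = "p1")[1, ]
  span <- map_aar_to_columns(g, "p1", aar)
  expect_equal(span, list(col_start = 0L, col_end = 4L))

  g2 <- toy_group(c(p1 = "-QQQQAA", p2 = "WQQQQAA"))
  aar2 <- detect_aars(g2$sequences[["p1"]], protein_id = "p1")[1, ]
  expect_equal(map_aar_to_columns(g2, "p1", aar2),
               list(col_start = 1L, col_end = 5L))

  # round-trip: ungapped span content equals the repeat tract
  set.seed(83)
  cfg <- generator_config(seed = 83, n_species = 4, n_groups = 4,
                          protein_length_range = c(60, 100))
  b <- generate_bundle(cfg, parts = c("sequences", "alignments"))
  for (g3 in b$groups) for (id in names(g3$sequences)) {
    aars <- detect_aars(g3$sequences[[id]], protein_id = id)
    for (i in seq_len(nrow(aars))) {
      sp <- map_aar_to_columns(g3, id, aars[i, ])
      content <- gsub("-", "", substr(g3$msa[[id]], sp$col_start + 1, sp$col_end))
      expect_equal(content, strrep(aars$residue[i], aars$length[i]))
    }
  }
})

test_that("a repeat fails to align only when every other ortholog is mostly gaps", {
  rows <- c(p1 = "AAAAWW", p2 = "----WW", p3 = "----WW")
  g <- toy_group(rows)
  aar <- detect_aars(g$sequences[["p1"]], protein_id = "p1")[1, ]
  span <- map_aar_to_columns(g, "p1", aar)
  expect_equal(conservation_status(g, "p1", span), "fails_to_align")
  # one gap-free other member rescues it
  g2 <- toy_group(c(p1 = "AAAAWW", p2 = "AAAAWW", p3 = "----WW"))
  expect_equal(conservation_status(g2, "p1", span), "partially_aligned")
  # exactly-half gaps is not "filled with gaps" (strict inequality)
  g3 <- toy_group(c(p1 = "AAAAWW", p2 = "AA--WW"))
  expect_equal(conservation_status(g3, "p1", span, gap_frac_threshold = 0.5),
               "partially_aligned")
})

test_that("conserved long repeats require length 8 and eight supporting orthologs", {
  mk_group <- function(n_carrier, len = 8L) {
    # 10 members; carriers share the tract block, others are gapped there
    tract <- strrep("Q", len)
    gaps <- strrep("-", len)
    rows <- vapply(1:10, function(i)
      paste0("MSTW", if (i <= n_carrier) tract else gaps, "KLH"),
      character(1))
    names(rows) <- paste0("p", 1:10)
    toy_group(rows)
  }
  # perfectly conserved block of 8 -> reported for each carrier
  g <- mk_group(10)
  found <- find_conserved_long_aars(g)
  expect_setequal(unique(found$protein_id), paste0("p", 1:10))
  expect_true(all(found$n_supporting == 9))
  # length 7 is excluded ("longer than seven" is exclusive)
  expect_equal(nrow(find_conserved_long_aars(mk_group(10, len = 7L))), 0L)
  # support threshold: the focal carrier needs >= 8 *other* members
  for (k in c(7, 8, 9, 10)) {
    found_k <- find_conserved_long_aars(mk_group(k))
    # brute-force recount: each carrier sees k - 1 supporting others
    if (k - 1 >= 8) expect_setequal(unique(found_k$protein_id),
                                    paste0("p", seq_len(k)))
    else expect_equal(nrow(found_k), 0L)
  }
})

test_that("member identity over the span is recomputed correctly against a brute-force recount", {
  set.seed(89)
  cfg <- generator_config(seed = 89, n_species = 10, n_groups = 3,
                          conserved_repeat_prob = 0.5)
  b <- generate_bundle(cfg, parts = c("sequences", "alignments"))
  for (g in b$groups) {
    found <- find_conserved_long_aars(g)
    for (i in seq_len(nrow(found))) {
      cols <- (found$col_start[i] + 1):found$col_end[i]
      others <- setdiff(names(g$msa), found$protein_id[i])
      ident <- vapply(others, function(oid) {
        ch <- strsplit(g$msa[[oid]], "")[[1]][cols]
        mean(ch == found$residue[i])
      }, numeric(1))
      expect_equal(found$n_supporting[i], sum(ident >= 0.5))
      expect_equal(found$mean_identity[i], mean(ident), tolerance = 1e-12)
    }
  }
})

test_that("flanks extend up to 33 residues, truncated at ends and neighbouring repeats", {
  a <- data.frame(protein_id = "p", residue = "Q", start = 40L, end = 48L,
                  length = 8L, stringsAsFactors = FALSE)
  fl <- extract_flanks(200L, a)
  expect_equal(fl$start, c(7L, 48L))
  expect_equal(fl$end, c(40L, 81L))
  # repeat at the N-terminus: left flank vanishes
  a2 <- data.frame(protein_id = "p", residue = "Q", start = 0L, end = 5L,
                   length = 5L, stringsAsFactors = FALSE)
  fl2 <- extract_flanks(200L, a2)
  expect_equal(fl2$side, "right")
  expect_equal(c(fl2$start, fl2$end), c(5L, 38L))
  # the stretch between two nearby repeats is shared by both
  a3 <- data.frame(protein_id = "p", residue = c("Q", "A"),
                   start = c(10L, 30L), end = c(14L, 34L),
                   length = c(4L, 4L), stringsAsFactors = FALSE)
  fl3 <- extract_flanks(200L, a3)
  right1 <- fl3[fl3$aar_index == 1 & fl3$side == "right", ]
  left2 <- fl3[fl3$aar_index == 2 & fl3$side == "left", ]
  expect_equal(c(right1$start, right1$end), c(14L, 30L))
  expect_equal(c(left2$start, left2$end), c(14L, 30L))
  # property: no flank overlaps any repeat of its protein
  set.seed(97)
  for (i in 1:30) {
    s <- repeat_enriched_protein(sample(60:200, 1))
    aa <- detect_aars(s, protein_id = "p")
    if (nrow(aa) == 0) next
    fl4 <- extract_flanks(nchar(s), aa)
    for (j in seq_len(nrow(fl4)))
      expect_true(all(fl4$end[j] <= aa$start | fl4$start[j] >= aa$end))
  }
})

test_that("protein column spans project onto codon columns and translate back", {
  g <- toy_group(c(p1 = "QQQQWW", p2 = "QQQQWW"))
  rows <- project_to_codons(g, 2L, 4L)
  expect_equal(nchar(rows[[1]]), 6L)
  expect_equal(aarscan:::translate_cds(rows[["p1"]]), "QQ")
  expect_equal(rows[["p1"]], substr(g$codon_msa[["p1"]], 7, 12))
  # a gap column in one member excludes that codon from its pair listwise
  g2 <- toy_group(c(p1 = "QQAQ", p2 = "QQ-Q"))
  rows2 <- project_to_codons(g2, 0L, 4L)
  r <- ng86_dnds(rows2[["p1"]], rows2[["p2"]])
  expect_equal(r$n_codons_used, 3L)
})

test_that("flank-vs-whole comparison recovers relaxed flank constraint and reports by species", {
  cfg <- generator_config(seed = 131, n_species = 6, n_groups = 10,
                          protein_length_range = c(100, 160),
                          flank_relaxation = 4)
  b <- generate_bundle(cfg, parts = c("sequences", "alignments"))
  fw <- flank_vs_whole_comparison(b$groups)
  d <- fw$per_protein
  expect_true(all(c("whole_dnds", "flank_dnds", "species") %in% names(d)))
  fl <- d$flank_dnds[is.finite(d$flank_dnds)]
  wh <- d$whole_dnds[is.finite(d$whole_dnds)]
  expect_gt(median(fl), median(wh))
  tr <- mann_whitney_u(fl, wh)
  expect_lt(tr$p_value, 0.05)
  # per-species reports exist and carry medians
  expect_true(length(fw$tests) >= 1)
  expect_true(all(vapply(fw$tests, function(t) is.numeric(t$median_flank),
                         logical(1))))
  expect_true(all(fw$flank_positive_fraction >= 0 &
                    fw$flank_positive_fraction <= 1, na.rm = TRUE))
})

test_that("a single degenerate group still yields a flagged comparison", {
  g <- toy_group(c(p1 = "WWAAAAWWWWWWWWWW", p2 = "WWAAAAWWWWWWWWWW"),
                 species = c("s1", "s2"))
  fw <- flank_vs_whole_comparison(list(g))
  expect_equal(nrow(fw$per_protein), 2L)
  if (length(fw$tests) > 0)
    expect_true(all(vapply(fw$tests, `[[`, logical(1), "unreliable")))
})
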