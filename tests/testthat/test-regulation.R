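test_that("expression normalisation equalises tissue means while preserving the grand mean", {
  set.seed(3)
  raw <- matrix(2^rnorm(200, 8, 1), 50, 4,
                dimnames = list(paste0("g", 1:50), paste0("t", 1:4)))
  norm0 <- normalize_expression(raw)
  raw2 <- raw
  raw2[, 2] <- raw2[, 2] * 2   # one tissue uniformly doubled on raw scale
  norm <- normalize_expression(raw2)
  cm <- colMeans(norm)
  expect_true(all(abs(cm - mean(norm)) < 1e-9))
  # doubling is undone up to a uniform grand-mean shift
  diffs <- norm - norm0
  expect_lt(diff(range(diffs)), 1e-9)
  # masked (absent) entries stay NA and are excluded from means
  pres <- matrix(TRUE, 50, 4); pres[1, 1] <- FALSE
  norm2 <- normalize_expression(raw, pres)
  expect_true(is.na(norm2[1, 1]))
  expect_error(normalize_expression(matrix(c(-1, 2, 3, 4), 2, 2)), "positive")
})

test_that("the tissue specificity index hits its analytic anchor points", {
  expect_equal(tissue_specificity_index(c(8, 8, 8, 8))$tsi, 0)
  expect_equal(tissue_specificity_index(c(8, 0, 0, 0, 0))$tsi, 1)
  expect_equal(tissue_specificity_index(c(4, 2))$tsi, 0.5)
  # negative values floored, flagged
  r <- tissue_specificity_index(c(4, -1))
  expect_true(r$floored)
  expect_equal(r$tsi, 1)
  # undefined cases
  expect_true(is.na(tissue_specificity_index(c(5))$tsi))
  expect_true(is.na(tissue_specificity_index(c(0, 0, 0))$tsi))
  expect_true(is.na(tissue_specificity_index(c(NA, 7))$tsi))
  # range property
  set.seed(13)
  for (i in 1:50) {
    x <- runif(sample(2:10, 1), 0, 20)
    tsi <- tissue_specificity_index(x)$tsi
    expect_gte(tsi, 0); expect_lte(tsi, 1)
  }
})

test_that("per-locus aggregation is the unweighted probe mean", {
  pm <- data.frame(probe = c("p1", "p2", "p3"), locus = c("A", "A", "B"))
  v <- data.frame(probe = c("p1", "p2", "p3"), value = c(0.2, 0.4, 0.9))
  agg <- aggregate_per_locus(v, pm)
  expect_equal(agg$value[agg$locus == "A"], 0.3)
  expect_equal(agg$value[agg$locus == "B"], 0.9)
  expect_error(aggregate_per_locus(v, data.frame(probe = c("p1", "p1"),
                                                 locus = c("A", "B"))),
               "more than one")
  # group-by oracle on random assignments
  set.seed(29)
  probes <- paste0("pr", 1:60)
  pm2 <- data.frame(probe = probes, locus = sample(LETTERS[1:10], 60, TRUE))
  v2 <- data.frame(probe = probes, value = rnorm(60))
  agg2 <- aggregate_per_locus(v2, pm2)
  ref <- tapply(v2$value, pm2$locus, mean)
  expect_equal(agg2$value, as.numeric(ref[agg2$locus]))
})

test_that("half-life comparison runs Welch's test and flags degenerate classes", {
  hl <- data.frame(locus = paste0("g", 1:40), hours = c(rexp(20, 1/3), rexp(20, 1/5)))
  fl <- data.frame(locus = paste0("g", 1:40), is_rcp = rep(c(TRUE, FALSE), each = 20))
  r <- compare_rcp_half_lives(hl, fl)
  expect_false(r$unreliable)
  expect_equal(r$mean_rcp, mean(hl$hours[1:20]))
  one <- compare_rcp_half_lives(
    data.frame(locus = c("a", "b", "c"), hours = c(1, 5, 6)),
    data.frame(locus = c("a", "b", "c"), is_rcp = c(TRUE, FALSE, FALSE)))
  expect_true(one$unreliable)
  expect_error(compare_rcp_half_lives(
    data.frame(locus = "a", hours = 1),
    data.frame(locus = "a", is_rcp = TRUE)), "nonempty")
})

test_that("shorter repeat-protein half-lives are detected at the generator's settings", {
  set.seed(37)
  n <- 2000
  is_rcp <- rep(c(TRUE, FALSE), each = n / 2)
  sig <- replicate(20, {
    hours <- rexp(n, rate = 1 / ifelse(is_rcp, 0.8 * 4, 4))
    hl <- data.frame(locus = paste0("g", 1:n), hours = hours)
    fl <- data.frame(locus = paste0("g", 1:n), is_rcp = is_rcp)
    r <- compare_rcp_half_lives(hl, fl)
    r$p_value < 0.01 && r$mean_rcp < r$mean_nonrcp
  })
  expect_gte(mean(sig), 0.95)
})

test_that("exons are constitutive only when present in every model of the gene", {
  m <- data.frame(gene = "g1",
                  model = c("m1", "m1", "m1", "m2", "m2"),
                  start = c(0, 100, 200, 0, 200),
                  end = c(50, 150, 250, 50, 250),
                  strand = "+")
  cls <- classify_exons(m)
  expect_equal(cls$exon_class[cls$start == 0], "constitutive")
  expect_equal(cls$exon_class[cls$start == 100], "alternative")
  expect_equal(cls$exon_class[cls$start == 200], "constitutive")
  # single-model genes: all constitutive
  single <- classify_exons(data.frame(gene = "g2", model = "m1",
                                      start = c(0, 100), end = c(60, 160)))
  expect_true(all(single$exon_class == "constitutive"))
  # brute-force interval-intersection oracle on random model sets
  set.seed(43)
  for (i in 1:20) {
    n_models <- sample(1:3, 1)
    pool <- data.frame(start = seq(0, 900, 100), end = seq(60, 960, 100))
    rows <- do.call(rbind, lapply(seq_len(n_models), function(m_) {
      k <- sample(4:10, 1)
      idx <- sort(sample(nrow(pool), k))
      data.frame(gene = "g", model = paste0("m", m_),
                 start = pool$start[idx], end = pool$end[idx])
    }))
    cls2 <- classify_exons(rows)
    for (j in seq_len(nrow(cls2))) {
      carried <- sapply(unique(rows$model), function(m_)
        any(rows$model == m_ & rows$start == cls2$start[j] &
              rows$end == cls2$end[j]))
      expect_equal(cls2$exon_class[j] == "constitutive", all(carried))
    }
  }
})

test_that("exon segments partition residues with junction codons going upstream", {
  # 10 residues, exons of 17 + 13 nt: codon 6 (bases 15-17) splits 2|1
  aars <- detect_aars("QQQQQACDEF", protein_id = "p")
  segs <- exon_segment_rrpk(10L, aars, c(17L, 13L),
                            c("constitutive", "alternative"))
  expect_equal(segs$n_residues, c(6L, 4L))       # residue 5 (0-based) upstream
  expect_equal(sum(segs$n_residues), 10L)
  expect_equal(sum(segs$n_repeat_residues), sum(aars$length))
  expect_equal(segs$rrpk[1], 1000 * 5 / 6)
  # single exon reproduces the protein RRPK
  one <- exon_segment_rrpk(10L, aars, 30L, "constitutive")
  expect_equal(one$rrpk, compute_rrpk(10, aars))
  # retained stop codon tolerated
  ok <- exon_segment_rrpk(10L, aars, c(17L, 16L), c("c", "c"))
  expect_equal(sum(ok$n_residues), 10L)
  expect_error(exon_segment_rrpk(10L, aars, c(17L, 10L), c("c", "c")), "sum")
  # random structures: per-class repeat residues equal a brute-force recount
  set.seed(59)
  for (i in 1:20) {
    s <- repeat_enriched_protein(60)
    a <- detect_aars(s, protein_id = "p")
    n_ex <- sample(1:4, 1)
    cuts <- sort(sample(seq(3, 177, 3), n_ex - 1))
    lens <- diff(c(0, cuts, 180))
    cls <- sample(c("alternative", "constitutive"), n_ex, TRUE)
    segs2 <- exon_segment_rrpk(60L, a, lens, cls)
    expect_equal(sum(segs2$n_residues), 60L)
    expect_equal(sum(segs2$n_repeat_residues), sum(a$length))
  }
})

test_that("hotspot neighbourhood uses 1-bp interval overlap and Fisher's test", {
  genes <- data.frame(chrom = "chr1", start = c(100L, 300L, 600L),
                      end = c(200L, 400L, 700L), gene = c("a", "b", "c"))
  hs <- data.frame(chrom = "chr1", start = 199L, end = 250L)
  flags <- data.frame(gene = c("a", "b", "c"), is_rcp = c(TRUE, FALSE, FALSE))
  r <- hotspot_neighbor_enrichment(genes, hs, flags)
  expect_equal(r$table["rcp", "neighbouring"], 1L)
  expect_equal(sum(r$table), 3L)
  expect_equal(r$fraction_rcp, 1)
  expect_equal(r$fraction_nonrcp, 0)
  # half-open convention: a hotspot ending at a gene start does not overlap
  hs2 <- data.frame(chrom = "chr1", start = 50L, end = 100L)
  r2 <- hotspot_neighbor_enrichment(genes, hs2, flags)
  expect_equal(sum(r2$table[, "neighbouring"]), 0L)
  expect_true(r2$degenerate)
  # brute-force all-pairs overlap oracle on random intervals
  set.seed(61)
  for (i in 1:10) {
    g2 <- data.frame(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                     start = sample(0:5000, 30), gene = paste0("g", 1:30))
    g2$end <- g2$start + sample(50:400, 30, TRUE)
    h2 <- data.frame(chrom = sample(c("chr1", "chr2"), 8, TRUE),
                     start = sample(0:5000, 8))
    h2$end <- h2$start + sample(50:400, 8, TRUE)
    fl2 <- data.frame(gene = g2$gene, is_rcp = runif(30) < 0.5)
    r3 <- hotspot_neighbor_enrichment(g2, h2, fl2)
    brute <- sapply(seq_len(30), function(k)
      any(h2$chrom == g2$chrom[k] & h2$start < g2$end[k] & h2$end > g2$start[k]))
    expect_equal(sum(r3$table[, "neighbouring"]), sum(brute))
  }
})
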