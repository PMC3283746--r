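# Seeded experiment wrappers shared by the calibration/power tests. Problem
# sizes are desk-scale study conditions (documented in the methods
# vignette): 10 species x 80 ortholog groups for the repeat-GC coupling,
# 6 species x 12 groups for the flank-relaxation recovery, and 2 species x
# 40 groups with short tracts for the disorder permutation calibration.

rrpk_gc_experiment <- function(seed, coupled = TRUE) {
  cfg <- if (coupled) generator_config(seed = seed) else
    generator_config(seed = seed, slippage_gc_coupling = 0,
                     base_repeat_residues = 22)
  b <- generate_bundle(cfg, parts = "sequences")
  ss <- species_summary(scan_proteins(b$proteins)$profiles)
  tr <- pearson_cor(ss$mean_gc, ss$mean_rrpk)
  c(r = tr$estimate, p = tr$p_value)
}

flank_relaxation_experiment <- function(seed, relaxation) {
  cfg <- generator_config(seed = seed, n_species = 6, n_groups = 12,
                          protein_length_range = c(100, 160),
                          flank_relaxation = relaxation)
  b <- generate_bundle(cfg, parts = c("sequences", "alignments"))
  fw <- flank_vs_whole_comparison(b$groups)
  d <- fw$per_protein
  fl <- d$flank_dnds[is.finite(d$flank_dnds)]
  wh <- d$whole_dnds[is.finite(d$whole_dnds)]
  tr <- mann_whitney_u(fl, wh)
  c(p = tr$p_value, flank_gt_whole = as.numeric(median(fl) > median(wh)))
}

disorder_null_experiment <- function(seed, p_in, p_bg, n_trials = 200L) {
  cfg <- generator_config(seed = seed, n_species = 2, n_groups = 40,
                          slippage_gc_coupling = 0,
                          base_repeat_residues = 7.5,
                          disorder_in_repeat_p = c(a = p_in, b = p_in),
                          disorder_background_p = c(a = p_bg, b = p_bg))
  b <- generate_bundle(cfg, parts = c("sequences", "disorder"))
  sc <- scan_proteins(b$proteins)
  rcp <- sc$profiles[sc$profiles$is_rcp, c("protein_id", "length")]
  names(rcp)[1] <- "id"
  random_segment_null(sc$aars, rcp, b$disorder$a, n_trials = n_trials,
                      seed = seed + 10000L)
}
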