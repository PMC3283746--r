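# End-to-end orchestration over an in-memory bundle: scan -> conservation/
# dN/dS -> disorder -> regulation -> summary report. The library functions
# are the interface; run_analysis() wires them in dependency order and
# returns every intermediate table, optionally writing the TSV report set.

#' Run the full repeat analysis over a bundle
#'
#' Stages: (1) repeat scan and per-species RRPK/GC summary with Pearson
#' correlation and a Grubbs outlier call on species mean RRPK; (2) regional
#' (protein-thirds) profile and residue composition; (3) ortholog
#' conservation calls, conserved long repeats, and flank versus
#' whole-protein dN/dS; (4) fully-disordered repeat fractions per
#' annotation track with the random-segment permutation test; (5)
#' regulation statistics (tissue specificity, half-lives, splice classes,
#' hotspot enrichment). Stages whose inputs are absent from the bundle are
#' skipped.
#'
#' @param bundle An `aar_bundle` from [generate_bundle()] (or an
#'   equivalently shaped list read from files).
#' @param min_len Minimum repeat length (default 4).
#' @param n_trials Permutation trials for the disorder test (default 1000).
#' @param seed Seed for the permutation null (default: the bundle's).
#' @param out Optional directory; when given, every report table is
#'   written as TSV with seed-carrying headers.
#' @return A list of class `aar_report` with elements `profiles`, `aars`,
#'   `species_summary`, `rrpk_gc_correlation`, `grubbs_outlier`,
#'   `regional`, `composition`, `conservation`, `conserved_long`,
#'   `flank_whole`, `disorder_tests`, `regulation`.
#' @export
run_analysis <- function(bundle, min_len = 4L, n_trials = 1000L,
                         seed = NULL, out = NULL) {
  if (is.null(seed)) seed <- bundle$config$seed
  scan <- scan_proteins(bundle$proteins, min_len)
  report <- list(profiles = scan$profiles, aars = scan$aars)
  report$species_summary <- species_summary(scan$profiles)

  ss <- report$species_summary
  if (nrow(ss) >= 3L && stats::sd(ss$mean_rrpk) > 0 && stats::sd(ss$mean_gc) > 0) {
    report$rrpk_gc_correlation <- pearson_cor(ss$mean_gc, ss$mean_rrpk)
    report$grubbs_outlier <- grubbs_test(ss$mean_rrpk)
  }

  regional <- lapply(seq_len(nrow(bundle$proteins)), function(i) {
    p <- bundle$proteins[i, ]
    if (p$length < 3L) return(NULL)
    a <- scan$aars[scan$aars$protein_id == p$id, , drop = FALSE]
    cbind(data.frame(protein_id = p$id, species = p$species,
                     stringsAsFactors = FALSE),
          regional_profile(p$sequence, a, p$cds))
  })
  report$regional <- do.call(rbind, regional)
  report$composition <- aar_residue_composition(scan$aars, bundle$proteins)

  if (!is.null(bundle$groups)) {
    cons <- lapply(bundle$groups, group_conservation, min_len = min_len)
    report$conservation <- do.call(rbind, c(cons, make.row.names = FALSE))
    n_members <- vapply(bundle$groups, function(g) nrow(g$members), integer(1))
    eligible <- bundle$groups[n_members >= 9L]
    if (length(eligible) > 0L) {
      cl <- lapply(eligible, find_conserved_long_aars, min_len = min_len)
      report$conserved_long <- do.call(rbind, c(cl, make.row.names = FALSE))
    }
    report$flank_whole <- flank_vs_whole_comparison(bundle$groups, min_len)
  }

  if (!is.null(bundle$disorder)) {
    rcp <- scan$profiles[scan$profiles$is_rcp, c("protein_id", "length")]
    names(rcp)[1] <- "id"
    report$disorder_tests <- lapply(bundle$disorder, function(ann) {
      if (nrow(scan$aars) == 0L) return(NULL)
      random_segment_null(scan$aars, rcp, ann, n_trials = n_trials,
                          seed = seed)
    })
  }

  if (!is.null(bundle$expression)) {
    norm <- normalize_expression(bundle$expression$raw,
                                 bundle$expression$present)
    tsi <- tsi_table(norm)
    names(tsi)[1] <- "probe"
    tsi_locus <- aggregate_per_locus(
      data.frame(probe = tsi$probe, value = tsi$tsi),
      bundle$expression$probe_map)
    hl_locus <- aggregate_per_locus(
      data.frame(probe = bundle$half_lives$probe,
                 value = bundle$half_lives$hours),
      bundle$expression$probe_map)
    names(hl_locus)[2] <- "hours"
    flags <- bundle$rcp_flags
    hl_test <- if (any(flags$is_rcp) && any(!flags$is_rcp))
      compare_rcp_half_lives(
        data.frame(locus = hl_locus$locus, hours = hl_locus$hours),
        data.frame(locus = flags$gene, is_rcp = flags$is_rcp)) else NULL
    tsi_m <- merge(tsi_locus, flags, by.x = "locus", by.y = "gene")
    tsi_test <- if (sum(tsi_m$is_rcp, na.rm = TRUE) >= 2L &&
                    sum(!tsi_m$is_rcp, na.rm = TRUE) >= 2L)
      welch_t(tsi_m$value[tsi_m$is_rcp & !is.na(tsi_m$value)],
              tsi_m$value[!tsi_m$is_rcp & !is.na(tsi_m$value)]) else NULL

    exon_cls <- classify_exons(bundle$gene_models$models)
    segs <- list()
    focal <- bundle$proteins[match(flags$gene, bundle$proteins$id), ]
    for (i in seq_len(nrow(focal))) {
      em <- bundle$gene_models$exon_map[
        bundle$gene_models$exon_map$gene == focal$id[i], , drop = FALSE]
      a <- scan$aars[scan$aars$protein_id == focal$id[i], , drop = FALSE]
      s <- exon_segment_rrpk(focal$length[i], a, em$length_nt, em$exon_class)
      s$gene <- focal$id[i]
      segs[[length(segs) + 1L]] <- s
    }
    segs <- do.call(rbind, segs)
    splice_test <- if (sum(segs$exon_class == "alternative") >= 2L &&
                       sum(segs$exon_class == "constitutive") >= 2L)
      splice_class_comparison(segs) else NULL
    hs <- hotspot_neighbor_enrichment(bundle$genes_bed, bundle$hotspots_bed,
                                      flags)
    report$regulation <- list(tsi = tsi_locus, tsi_test = tsi_test,
                              half_lives = hl_locus, half_life_test = hl_test,
                              exon_segments = segs, splice_test = splice_test,
                              exon_classes = exon_cls, hotspot = hs)
  }

  class(report) <- "aar_report"
  if (!is.null(out)) write_report(report, out, seed)
  report
}

write_report <- function(report, out, seed) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, name) {
    if (is.null(df) || nrow(df) == 0L) return(invisible(NULL))
    d <- df
    if (all(c("start", "end") %in% names(d))) {
      d$start_1based <- d$start + 1L
      d$end_1based <- d$end
    }
    write_tsv(d, file.path(out, paste0(name, ".tsv")), seed)
  }
  emit(report$profiles, "profiles")
  emit(report$aars, "aars")
  emit(report$species_summary, "species_summary")
  emit(report$regional, "regional")
  emit(report$composition, "composition")
  emit(report$conservation, "conservation")
  emit(report$conserved_long, "conserved_long_aars")
  if (!is.null(report$flank_whole)) emit(report$flank_whole$per_protein,
                                         "flank_whole_dnds")
  if (!is.null(report$disorder_tests)) {
    dt <- report$disorder_tests
    dt <- dt[!vapply(dt, is.null, logical(1))]
    if (length(dt) > 0L)
      emit(data.frame(track = names(dt),
                      observed_fraction = vapply(dt, `[[`, numeric(1),
                                                 "observed_fraction"),
                      empirical_p = vapply(dt, `[[`, numeric(1), "empirical_p"),
                      n_trials = vapply(dt, `[[`, numeric(1), "n_trials"),
                      seed = seed, stringsAsFactors = FALSE),
           "disorder_tests")
  }
  if (!is.null(report$regulation)) {
    emit(report$regulation$tsi, "tsi")
    emit(report$regulation$exon_segments, "exon_segments")
  }
  invisible(out)
}

#' @export
print.aar_report <- function(x, ...) {
  cat("Repeat analysis report\n")
  cat("  proteins:", nrow(x$profiles), " repeats:", nrow(x$aars), "\n")
  if (!is.null(x$rrpk_gc_correlation))
    cat("  species RRPK~GC: r =", format(x$rrpk_gc_correlation$estimate),
        ", p =", format.pval(x$rrpk_gc_correlation$p_value), "\n")
  if (!is.null(x$disorder_tests))
    for (tr in names(x$disorder_tests))
      if (!is.null(x$disorder_tests[[tr]]))
        cat("  disorder (", tr, "): observed ",
            format(x$disorder_tests[[tr]]$observed_fraction), ", p ",
            format(x$disorder_tests[[tr]]$empirical_p), "\n", sep = "")
  invisible(x)
}
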