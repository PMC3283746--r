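# Transcript-level regulation of repeat-containing proteins: expression
# normalisation and tissue specificity, mRNA half-life comparison,
# splice-class repeat content, and recombination-hotspot proximity.

#' Normalise an expression matrix
#'
#' Present (above-background) values are log2-transformed; each tissue's
#' mean is subtracted and the grand mean of all present log values is added
#' back, so tissues become directly comparable while the overall scale is
#' preserved. Absent entries stay `NA`.
#'
#' @param raw Gene x tissue matrix of positive raw-scale values.
#' @param present Logical matrix of the same shape (above-background
#'   "Presence" calls); defaults to all present.
#' @return Matrix of normalised log2 values with `NA` for absent entries.
#'   After normalisation every tissue's mean over present entries equals
#'   the grand mean.
#' @export
normalize_expression <- function(raw, present = NULL) {
  stopifnot(is.matrix(raw), ncol(raw) >= 2L)
  if (is.null(present)) present <- !is.na(raw)
  stopifnot(all(dim(present) == dim(raw)))
  if (any(raw[present] <= 0)) stop("raw values must be positive where present")
  lg <- matrix(NA_real_, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  lg[present] <- log2(raw[present])
  col_means <- colMeans(lg, na.rm = TRUE)
  grand <- mean(lg, na.rm = TRUE)
  out <- sweep(lg, 2L, col_means, "-") + grand
  out
}

#' Tissue specificity index
#'
#' TSI = sum_i (1 - x_i / x_max) / (N - 1) over the N usable tissues; 0 for
#' uniform expression, 1 when exactly one tissue is expressed. Values are
#' floored at 0 first (normalised log values can go slightly negative);
#' genes with fewer than 2 usable tissues or x_max <= 0 are undefined.
#'
#' @param x Per-tissue expression values for one gene (`NA` = absent).
#' @return A list: `tsi` (`NA` when undefined), `n_tissues_used`,
#'   `floored` (TRUE when any value was raised to 0).
#' @export
tissue_specificity_index <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  floored <- any(x < 0)
  x <- pmax(x, 0)
  if (n < 2L || max(x) <= 0)
    return(list(tsi = NA_real_, n_tissues_used = n, floored = floored))
  list(tsi = sum(1 - x / max(x)) / (n - 1), n_tissues_used = n,
       floored = floored)
}

#' Per-gene tissue specificity for a normalised matrix
#'
#' @param mat Normalised gene x tissue matrix ([normalize_expression()]).
#' @return Data frame: `gene`, `tsi`, `n_tissues_used`, `floored`.
#' @export
tsi_table <- function(mat) {
  res <- apply(mat, 1L, tissue_specificity_index)
  data.frame(gene = rownames(mat),
             tsi = vapply(res, `[[`, numeric(1), "tsi"),
             n_tissues_used = vapply(res, `[[`, integer(1), "n_tissues_used"),
             floored = vapply(res, `[[`, logical(1), "floored"),
             stringsAsFactors = FALSE)
}

#' Aggregate per-probe statistics to loci
#'
#' Loci with multiple probes get the unweighted mean of their probes'
#' values; loci without probes are absent from the output.
#'
#' @param values Data frame with columns `probe` and `value`.
#' @param probe_map Data frame with columns `probe` and `locus` (each probe
#'   maps to at most one locus).
#' @return Data frame: `locus`, `value`, `n_probes`.
#' @export
aggregate_per_locus <- function(values, probe_map) {
  if (anyDuplicated(probe_map$probe))
    stop("a probe maps to more than one locus")
  m <- merge(values, probe_map, by = "probe")
  if (nrow(m) == 0L)
    return(data.frame(locus = character(0), value = numeric(0),
                      n_probes = integer(0), stringsAsFactors = FALSE))
  agg <- tapply(m$value, m$locus, mean, na.rm = TRUE)
  cnt <- tapply(m$value, m$locus, length)
  data.frame(locus = names(agg), value = as.numeric(agg),
             n_probes = as.integer(cnt), stringsAsFactors = FALSE)
}

#' Compare mRNA half-lives of RCP and non-RCP transcripts
#'
#' Welch's t-test on the two half-life samples.
#'
#' @param half_lives Data frame: `locus`, `hours`.
#' @param rcp_flags Data frame: `locus`, `is_rcp` (logical).
#' @return An `aar_test_report` with group means and direction;
#'   `extra$unreliable` is TRUE when either class has fewer than 2 loci.
#' @export
compare_rcp_half_lives <- function(half_lives, rcp_flags) {
  m <- merge(half_lives, rcp_flags, by = "locus")
  a <- m$hours[m$is_rcp]
  b <- m$hours[!m$is_rcp]
  if (length(a) == 0L || length(b) == 0L) stop("both classes must be nonempty")
  if (length(a) < 2L || length(b) < 2L) {
    tr <- new_test_report("Welch two-sample t-test", NA_real_, NA_real_,
                          c(length(a), length(b)),
                          extra = list(mean_a = mean(a), mean_b = mean(b),
                                       unreliable = TRUE))
    return(tr)
  }
  tr <- welch_t(a, b)
  tr$unreliable <- FALSE
  tr$mean_rcp <- mean(a)
  tr$mean_nonrcp <- mean(b)
  tr
}

#' Classify exons as constitutive or alternative
#'
#' An exon (identified by its exact genomic interval) is constitutive iff
#' the identical interval appears in every gene model of its gene;
#' otherwise it is alternative. A gene is alternatively spliced iff it has
#' at least two models; single-model genes have only constitutive exons.
#' Genes whose models disagree on strand are dropped with a warning.
#'
#' @param models Data frame: `gene`, `model`, `start`, `end` (0-based
#'   half-open genomic coordinates), optional `strand`.
#' @return Data frame of distinct exon intervals per gene with
#'   `exon_class` (`"constitutive"`/`"alternative"`) and `n_models` of the
#'   gene.
#' @export
classify_exons <- function(models) {
  stopifnot(all(c("gene", "model", "start", "end") %in% names(models)))
  if ("strand" %in% names(models)) {
    bad <- tapply(models$strand, models$gene,
                  function(s) length(unique(s)) > 1L)
    if (any(bad)) {
      warning("dropping genes with strand-discordant models: ",
              paste(names(bad)[bad], collapse = ", "))
      models <- models[!(models$gene %in% names(bad)[bad]), , drop = FALSE]
    }
  }
  out <- lapply(split(models, models$gene), function(d) {
    n_models <- length(unique(d$model))
    key <- paste(d$start, d$end)
    n_carrying <- tapply(d$model, key, function(m) length(unique(m)))
    u <- d[!duplicated(key), , drop = FALSE]
    uk <- paste(u$start, u$end)
    data.frame(gene = u$gene, start = u$start, end = u$end,
               exon_class = ifelse(n_carrying[uk] == n_models,
                                   "constitutive", "alternative"),
               n_models = n_models, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-exon-segment repeat content of a protein
#'
#' Maps every residue to the coding exon containing the first base of its
#' codon (codons split across a junction are assigned to the upstream
#' exon), then computes RRPK per exon segment; a repeat spanning a segment
#' boundary contributes its residues to each side.
#'
#' @param protein_length Protein length in residues.
#' @param aars Repeat table for the protein.
#' @param exon_lengths Coding-exon lengths in nucleotides, in transcript
#'   (5' to 3') order; must sum to 3 x protein_length (+3 allowed for a
#'   retained stop codon, assigned to the last exon).
#' @param exon_classes Character vector parallel to `exon_lengths`
#'   (`"constitutive"`/`"alternative"`).
#' @return Data frame: one row per exon with residue coordinates `start`,
#'   `end` (0-based half-open), `exon_class`, `n_repeat_residues`, `rrpk`.
#'   Exons encoding no complete codon start are dropped.
#' @export
exon_segment_rrpk <- function(protein_length, aars, exon_lengths, exon_classes) {
  stopifnot(length(exon_lengths) == length(exon_classes))
  total <- sum(exon_lengths)
  if (!(total == 3L * protein_length || total == 3L * protein_length + 3L))
    stop("exon lengths do not sum to the CDS length")
  cum <- cumsum(c(0L, exon_lengths))
  first_base <- 3L * (seq_len(protein_length) - 1L)
  exon_of <- findInterval(first_base, cum, left.open = FALSE,
                          rightmost.closed = FALSE)
  out <- list()
  for (e in seq_along(exon_lengths)) {
    res <- which(exon_of == e) - 1L   # 0-based residue indices
    if (length(res) == 0L) next
    lo <- min(res); hi <- max(res) + 1L
    nrep <- 0L
    if (nrow(aars) > 0L)
      nrep <- sum(pmax(0L, pmin(aars$end, hi) - pmax(aars$start, lo)))
    out[[length(out) + 1L]] <- data.frame(
      exon = e, exon_class = exon_classes[e], start = lo, end = hi,
      n_residues = hi - lo, n_repeat_residues = nrep,
      rrpk = 1000 * nrep / (hi - lo), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Splice-class repeat-content comparison
#'
#' Welch's t-test on per-segment RRPK values, alternative versus
#' constitutive exon segments pooled across genes.
#'
#' @param segments Row-bound output of [exon_segment_rrpk()] over genes.
#' @return An `aar_test_report`.
#' @export
splice_class_comparison <- function(segments) {
  a <- segments$rrpk[segments$exon_class == "alternative"]
  b <- segments$rrpk[segments$exon_class == "constitutive"]
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 segments per class")
  tr <- welch_t(a, b)
  tr$mean_alternative <- mean(a)
  tr$mean_constitutive <- mean(b)
  tr
}

#' Recombination-hotspot neighbourhood enrichment of RCP genes
#'
#' A gene is hotspot-neighbouring iff its genomic interval overlaps any
#' hotspot interval by at least 1 bp. Builds the 2x2 table (RCP status x
#' neighbouring status) and runs the two-sided Fisher exact test.
#'
#' @param genes Data frame: `chrom`, `start`, `end` (0-based half-open),
#'   `gene`.
#' @param hotspots Data frame: `chrom`, `start`, `end` (same convention).
#' @param rcp_flags Data frame: `gene`, `is_rcp`.
#' @return A list: `table` (2x2), `test` (`aar_test_report`),
#'   `fraction_rcp`, `fraction_nonrcp` (neighbouring fractions), and
#'   `degenerate` when no hotspot overlaps exist at all.
#' @export
hotspot_neighbor_enrichment <- function(genes, hotspots, rcp_flags) {
  g <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start + 1L, genes$end))
  neighbouring <- rep(FALSE, nrow(genes))
  if (nrow(hotspots) > 0L) {
    h <- GenomicRanges::GRanges(hotspots$chrom,
                                IRanges::IRanges(hotspots$start + 1L, hotspots$end))
    neighbouring <- IRanges::overlapsAny(g, h)
  }
  flags <- rcp_flags$is_rcp[match(genes$gene, rcp_flags$gene)]
  if (anyNA(flags)) stop("missing RCP flag for some genes")
  tab <- matrix(c(sum(flags & neighbouring), sum(flags & !neighbouring),
                  sum(!flags & neighbouring), sum(!flags & !neighbouring)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("rcp", "non_rcp"),
                                c("neighbouring", "not_neighbouring")))
  degenerate <- sum(neighbouring) == 0L
  test <- fisher_exact_2x2(tab)
  list(table = tab, test = test,
       fraction_rcp = if (sum(flags) > 0) mean(neighbouring[flags]) else NA_real_,
       fraction_nonrcp = if (sum(!flags) > 0) mean(neighbouring[!flags]) else NA_real_,
       degenerate = degenerate)
}
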