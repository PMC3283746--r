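# Ortholog groups: conservation of repeats within protein multiple
# alignments, flanking-region extraction, and codon-level projection for
# dN/dS estimation. Alignment columns use 0-based half-open spans, matching
# the residue coordinates of the repeat tables.

translate_cds <- function(cds) {
  gc <- Biostrings::GENETIC_CODE
  vapply(cds, function(s) {
    cod <- split_codons(toupper(s))
    aa <- gc[cod]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

ungap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Construct an ortholog group
#'
#' Validates that all alignment rows have equal width and that ungapping
#' each row reproduces the member's protein sequence; builds the codon
#' alignment by back-translation (each residue replaced by its codon, each
#' gap by `---`), after stripping a trailing stop codon from the CDS.
#'
#' @param group_id Group identifier.
#' @param members Data frame with columns `id` and `species`, one row per
#'   member, in alignment-row order.
#' @param msa Named character vector of aligned amino-acid strings
#'   (names = member ids, gap `-`).
#' @param cds Named character vector of unaligned coding sequences.
#' @return A list of class `ortholog_group` with elements `group_id`,
#'   `members`, `msa`, `codon_msa`, `sequences` (ungapped proteins) and
#'   `width` (alignment columns).
#' @export
ortholog_group <- function(group_id, members, msa, cds) {
  stopifnot(all(members$id %in% names(msa)), all(members$id %in% names(cds)))
  msa <- msa[members$id]
  cds <- cds[members$id]
  widths <- nchar(msa)
  if (length(unique(widths)) != 1L)
    stop("alignment rows of unequal width in group ", group_id, ": ",
         members$id[which(widths != widths[1])[1]])
  seqs <- ungap(msa)
  codon_msa <- character(length(msa))
  for (i in seq_along(msa)) {
    s <- toupper(cds[[i]])
    if (nchar(s) == 3L * (nchar(seqs[i]) + 1L)) {
      tail_codon <- substr(s, nchar(s) - 2L, nchar(s))
      if (Biostrings::GENETIC_CODE[tail_codon] %in% "*")
        s <- substr(s, 1L, nchar(s) - 3L)
    }
    if (nchar(s) != 3L * nchar(seqs[i]))
      stop("CDS/protein length mismatch for ", members$id[i],
           " in group ", group_id)
    if (translate_cds(s) != seqs[i])
      stop("CDS does not translate to the aligned protein for ",
           members$id[i], " in group ", group_id)
    codons <- split_codons(s)
    chars <- strsplit(msa[[i]], "", fixed = TRUE)[[1L]]
    row <- rep("---", length(chars))
    row[chars != "-"] <- codons
    codon_msa[i] <- paste(row, collapse = "")
  }
  names(codon_msa) <- members$id
  structure(list(group_id = group_id, members = members, msa = msa,
                 codon_msa = codon_msa, sequences = stats::setNames(seqs, members$id),
                 width = unname(widths[1])),
            class = "ortholog_group")
}

#' Map a repeat from residue coordinates to alignment columns
#'
#' @param group An `ortholog_group`.
#' @param member_id Id of the member carrying the repeat.
#' @param aar One row of a repeat table (residue coordinates on the
#'   ungapped sequence, 0-based half-open).
#' @return A list with `col_start`, `col_end` (0-based half-open column
#'   span): the minimal span whose ungapped content in the focal row is
#'   exactly the repeat tract.
#' @export
map_aar_to_columns <- function(group, member_id, aar) {
  chars <- strsplit(group$msa[[member_id]], "", fixed = TRUE)[[1L]]
  pos <- which(chars != "-")  # 1-based column of residue 0,1,...
  n <- length(pos)
  if (aar$start < 0L || aar$end > n) stop("repeat outside the member sequence")
  list(col_start = pos[aar$start + 1L] - 1L, col_end = pos[aar$end])
}

span_chars <- function(row, col_start, col_end) {
  strsplit(substr(row, col_start + 1L, col_end), "", fixed = TRUE)[[1L]]
}

#' Conservation status of a repeat within its ortholog alignment
#'
#' A repeat fails to align when, over its column span, every other member
#' is mostly gaps (gap fraction strictly greater than
#' `gap_frac_threshold`); otherwise it is partially aligned.
#'
#' @param group An `ortholog_group`.
#' @param member_id Focal member id.
#' @param span Column span from [map_aar_to_columns()].
#' @param gap_frac_threshold Gap fraction above which a member counts as
#'   gap-filled (default 0.5).
#' @return `"fails_to_align"` or `"partially_aligned"`.
#' @export
conservation_status <- function(group, member_id, span, gap_frac_threshold = 0.5) {
  others <- setdiff(names(group$msa), member_id)
  gap_fracs <- vapply(others, function(id) {
    ch <- span_chars(group$msa[[id]], span$col_start, span$col_end)
    mean(ch == "-")
  }, numeric(1))
  if (all(gap_fracs > gap_frac_threshold)) "fails_to_align" else "partially_aligned"
}

#' Conservation calls for every repeat in a group
#'
#' @inheritParams conservation_status
#' @param min_len Minimum repeat length (default 4).
#' @return Data frame: one row per repeat of every member, with its column
#'   span and conservation status.
#' @export
group_conservation <- function(group, min_len = 4L, gap_frac_threshold = 0.5) {
  out <- list()
  for (id in names(group$sequences)) {
    aars <- detect_aars(group$sequences[[id]], min_len, id)
    if (nrow(aars) == 0L) next
    for (i in seq_len(nrow(aars))) {
      span <- map_aar_to_columns(group, id, aars[i, ])
      out[[length(out) + 1L]] <- data.frame(
        group_id = group$group_id, protein_id = id,
        residue = aars$residue[i], start = aars$start[i], end = aars$end[i],
        length = aars$length[i],
        col_start = span$col_start, col_end = span$col_end,
        status = conservation_status(group, id, span, gap_frac_threshold),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(group_id = character(0), protein_id = character(0),
                      residue = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      col_start = integer(0), col_end = integer(0),
                      status = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Identify conserved long repeats in an ortholog group
#'
#' A repeat qualifies when (1) its length is at least `min_repeat_len`
#' (default 8, i.e. longer than seven residues) and (2) at least
#' `min_supporting` other members align over its column span with identity
#' of at least `min_identity`, where a member's identity is the fraction of
#' span columns carrying the repeat's amino acid (gaps count as
#' mismatches).
#'
#' @param group An `ortholog_group` with more than `min_supporting` members.
#' @param min_repeat_len Minimum repeat length (default 8).
#' @param min_supporting Minimum number of supporting other members
#'   (default 8).
#' @param min_identity Minimum per-member span identity (default 0.5).
#' @param min_len Repeat detection threshold (default 4).
#' @return Data frame of qualifying repeats with supporting-member count
#'   and mean identity over the other members.
#' @export
find_conserved_long_aars <- function(group, min_repeat_len = 8L,
                                     min_supporting = 8L, min_identity = 0.5,
                                     min_len = 4L) {
  stopifnot(length(group$msa) >= min_supporting + 1L)
  out <- list()
  for (id in names(group$sequences)) {
    aars <- detect_aars(group$sequences[[id]], min_len, id)
    if (nrow(aars) == 0L) next
    aars <- aars[aars$length >= min_repeat_len, , drop = FALSE]
    if (nrow(aars) == 0L) next
    for (i in seq_len(nrow(aars))) {
      span <- map_aar_to_columns(group, id, aars[i, ])
      others <- setdiff(names(group$msa), id)
      ident <- vapply(others, function(oid) {
        ch <- span_chars(group$msa[[oid]], span$col_start, span$col_end)
        mean(ch == aars$residue[i])
      }, numeric(1))
      n_support <- sum(ident >= min_identity)
      if (n_support >= min_supporting)
        out[[length(out) + 1L]] <- data.frame(
          group_id = group$group_id, protein_id = id,
          residue = aars$residue[i], start = aars$start[i],
          end = aars$end[i], length = aars$length[i],
          col_start = span$col_start, col_end = span$col_end,
          n_supporting = n_support, mean_identity = mean(ident),
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(group_id = character(0), protein_id = character(0),
                      residue = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      col_start = integer(0), col_end = integer(0),
                      n_supporting = integer(0), mean_identity = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Extract repeat flanking regions
#'
#' Up to `flank_len` residues on each side of every repeat, truncated at
#' the protein ends and at adjacent repeats. The stretch between two
#' repeats closer than 2 x `flank_len` is shared: it serves as the right
#' flank of the upstream repeat and the left flank of the downstream one
#' (each side truncated at the other repeat's boundary); identical regions
#' are deduplicated before aggregation so no codon is counted twice.
#' Zero-length regions are dropped.
#'
#' @param protein_length Length of the protein in residues.
#' @param aars Complete repeat table for the protein, in positional order.
#' @param flank_len Maximum flank length (default 33).
#' @return Data frame: `protein_id`, `aar_index`, `side`, `start`, `end`
#'   (0-based half-open residue coordinates).
#' @export
extract_flanks <- function(protein_length, aars, flank_len = 33L) {
  empty <- data.frame(protein_id = character(0), aar_index = integer(0),
                      side = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(aars) == 0L) return(empty)
  aars <- aars[order(aars$start), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(aars))) {
    prev_end <- if (i > 1L) aars$end[i - 1L] else 0L
    next_start <- if (i < nrow(aars)) aars$start[i + 1L] else protein_length
    l_start <- max(0L, aars$start[i] - flank_len, prev_end)
    r_end <- min(protein_length, aars$end[i] + flank_len, next_start)
    if (l_start < aars$start[i])
      out[[length(out) + 1L]] <- data.frame(
        protein_id = aars$protein_id[i], aar_index = i, side = "left",
        start = l_start, end = aars$start[i], stringsAsFactors = FALSE)
    if (aars$end[i] < r_end)
      out[[length(out) + 1L]] <- data.frame(
        protein_id = aars$protein_id[i], aar_index = i, side = "right",
        start = aars$end[i], end = r_end, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Project a protein-alignment column span onto the codon alignment
#'
#' @param group An `ortholog_group`.
#' @param col_start,col_end 0-based half-open protein-alignment columns.
#' @return Named character vector: the codon sub-alignment rows, columns
#'   `[3 col_start, 3 col_end)` of the codon alignment.
#' @export
project_to_codons <- function(group, col_start, col_end) {
  substring(group$codon_msa, 3L * col_start + 1L, 3L * col_end)
}

# All pairwise NG86 ratios over one codon sub-alignment. Returns a data
# frame of member pairs; gap/ambiguous/stop codons are filtered listwise
# per pair inside ng86_dnds.
pairwise_dnds <- function(codon_rows, focal = NULL) {
  ids <- names(codon_rows)
  n <- length(ids)
  pairs <- if (is.null(focal)) {
    which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  } else {
    fi <- match(focal, ids)
    cbind(row = fi, col = setdiff(seq_len(n), fi))
  }
  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    r <- ng86_dnds(codon_rows[[i]], codon_rows[[j]])
    out[[k]] <- data.frame(
      id_a = ids[i], id_b = ids[j], dn = r$dn, ds = r$ds, ratio = r$ratio,
      n_sites = r$n_sites, s_sites = r$s_sites, n_codons = r$n_codons_used,
      flag = r$flag, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Residue span -> columns for a (possibly non-repeat) region of a member:
# minimal column window containing the region's residues.
region_to_columns <- function(group, member_id, start, end) {
  chars <- strsplit(group$msa[[member_id]], "", fixed = TRUE)[[1L]]
  pos <- which(chars != "-")
  list(col_start = pos[start + 1L] - 1L, col_end = pos[end])
}

# Pooled NG86 counts (sd, nd, S, N) of one member against every other
# member over a set of codon rows; returns the Jukes-Cantor-corrected
# ratio of the pooled proportions, or NA when undefined.
pooled_focal_dnds <- function(codon_rows, focal, acc = NULL) {
  if (is.null(acc)) acc <- c(sd = 0, nd = 0, S = 0, N = 0)
  for (oid in setdiff(names(codon_rows), focal)) {
    r <- ng86_dnds(codon_rows[[focal]], codon_rows[[oid]])
    if (r$flag == "empty") next
    acc <- acc + c(r$sd, r$nd, r$s_sites, r$n_sites)
  }
  acc
}

ratio_from_counts <- function(acc) {
  if (acc[["S"]] <= 0 || acc[["N"]] <= 0) return(NA_real_)
  ps <- acc[["sd"]] / acc[["S"]]; pn <- acc[["nd"]] / acc[["N"]]
  if (ps >= 0.75 || pn >= 0.75) return(NA_real_)
  ds <- -0.75 * log(1 - 4 * ps / 3)
  dn <- -0.75 * log(1 - 4 * pn / 3)
  if (ds <= 0) return(if (dn > 0) Inf else NA_real_)
  dn / ds
}

# Drop a set of codon columns (0-based protein-alignment columns) from
# every row of a codon alignment.
drop_codon_columns <- function(codon_rows, drop_cols, width) {
  keep <- setdiff(seq_len(width) - 1L, drop_cols)
  vapply(codon_rows, function(row) {
    paste(substring(row, 3L * keep + 1L, 3L * keep + 3L), collapse = "")
  }, character(1))
}

#' Compare flank dN/dS with whole-protein dN/dS
#'
#' For every repeat-containing member of every group, computes (a) a
#' whole-protein dN/dS and (b) a flanking-region dN/dS, each as a single
#' Jukes-Cantor-corrected ratio of substitution counts pooled over all
#' ortholog pairs involving that member (and, for flanks, over its
#' deduplicated flank regions). Pooling counts before forming the ratio
#' avoids the small-region ratio bias that would otherwise confound the
#' comparison. The columns of the focal protein's own repeat tracts are
#' excluded from the whole-protein estimate: a homopolymer tract cannot
#' accumulate nonsynonymous differences while it exists as a repeat, so
#' leaving it in would depress the whole-protein rate for purely
#' definitional reasons rather than because of selection.
#'
#' Per species, flank and whole samples are compared with a Mann-Whitney U
#' test; the fraction of flank regions with pooled dN/dS > 1
#' (positive-selection candidates) is also reported.
#'
#' @param groups List of `ortholog_group` objects.
#' @param min_len Repeat detection threshold (default 4).
#' @param flank_len Maximum flank length (default 33).
#' @param exclude_tracts Exclude the focal repeat tract columns from the
#'   whole-protein estimate (default TRUE).
#' @return A list with `per_protein` (protein-level flank and whole
#'   ratios), `tests` (per-species `aar_test_report`s plus medians),
#'   `flank_positive_fraction` per species, and `flank_regions`
#'   (region-level pooled ratios). Species with fewer than 2 proteins in
#'   either sample are flagged unreliable.
#' @export
flank_vs_whole_comparison <- function(groups, min_len = 4L, flank_len = 33L,
                                      exclude_tracts = TRUE) {
  rows <- list()
  flank_region_rows <- list()
  for (g in groups) {
    for (id in names(g$sequences)) {
      seq_i <- g$sequences[[id]]
      aars <- detect_aars(seq_i, min_len, id)
      if (nrow(aars) == 0L) next
      sp <- g$members$species[match(id, g$members$id)]
      spans <- lapply(seq_len(nrow(aars)), function(i)
        map_aar_to_columns(g, id, aars[i, ]))
      whole_rows <- g$codon_msa
      if (exclude_tracts) {
        tract_cols <- unlist(lapply(spans, function(s)
          seq(s$col_start, s$col_end - 1L)))
        whole_rows <- drop_codon_columns(g$codon_msa, tract_cols, g$width)
      }
      whole_ratio <- ratio_from_counts(pooled_focal_dnds(whole_rows, id))
      fl <- extract_flanks(nchar(seq_i), aars, flank_len)
      fl <- unique(fl[c("protein_id", "start", "end")])
      facc <- NULL
      if (nrow(fl) > 0L) for (k in seq_len(nrow(fl))) {
        span <- region_to_columns(g, id, fl$start[k], fl$end[k])
        codon_rows <- project_to_codons(g, span$col_start, span$col_end)
        racc <- pooled_focal_dnds(codon_rows, id)
        flank_region_rows[[length(flank_region_rows) + 1L]] <- data.frame(
          group_id = g$group_id, protein_id = id, species = sp,
          start = fl$start[k], end = fl$end[k],
          dnds = ratio_from_counts(racc), stringsAsFactors = FALSE)
        facc <- if (is.null(facc)) racc else facc + racc
      }
      flank_ratio <- if (!is.null(facc)) ratio_from_counts(facc) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        group_id = g$group_id, protein_id = id, species = sp,
        whole_dnds = whole_ratio, flank_dnds = flank_ratio,
        n_flank_regions = nrow(fl), stringsAsFactors = FALSE)
    }
  }
  per_protein <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(group_id = character(0), protein_id = character(0),
               species = character(0), whole_dnds = numeric(0),
               flank_dnds = numeric(0), n_flank_regions = integer(0))
  flank_regions <- if (length(flank_region_rows) > 0L)
    do.call(rbind, flank_region_rows) else
    data.frame(group_id = character(0), protein_id = character(0),
               species = character(0), start = integer(0), end = integer(0),
               dnds = numeric(0))
  tests <- list()
  pos_frac <- list()
  for (sp in unique(per_protein$species)) {
    d <- per_protein[per_protein$species == sp, ]
    fl <- d$flank_dnds[is.finite(d$flank_dnds)]
    wh <- d$whole_dnds[is.finite(d$whole_dnds)]
    fr <- flank_regions$dnds[flank_regions$species == sp]
    fr <- fr[is.finite(fr)]
    pos_frac[[sp]] <- if (length(fr) > 0L) mean(fr > 1) else NA_real_
    if (length(fl) >= 1L && length(wh) >= 1L) {
      tr <- mann_whitney_u(fl, wh)
      tr$median_flank <- stats::median(fl)
      tr$median_whole <- stats::median(wh)
      tr$unreliable <- (length(fl) < 2L || length(wh) < 2L)
      tests[[sp]] <- tr
    }
  }
  list(per_protein = per_protein, flank_regions = flank_regions,
       tests = tests, flank_positive_fraction = unlist(pos_frac))
}
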