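# The 20 standard amino acids. 'X' (ambiguity) and any other letter break
# runs and never seed a repeat: an ambiguous residue cannot be asserted
# identical to its neighbours.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Amino acids encoded by GC-rich codons (alanine, glycine, proline).
GC_RICH_RESIDUES <- c("A", "G", "P")

empty_aar_table <- function() {
  data.frame(protein_id = character(0), residue = character(0),
             start = integer(0), end = integer(0), length = integer(0),
             stringsAsFactors = FALSE)
}

#' Detect tandem amino acid repeats (AARs) in a protein sequence
#'
#' An AAR is a maximal uninterrupted run of `min_len` or more identical
#' standard amino acids. Runs of `'X'` or any non-standard letter are never
#' reported, and such letters terminate a run.
#'
#' @param sequence Single amino-acid string (upper case one-letter codes).
#' @param min_len Minimum run length to report (default 4).
#' @param protein_id Identifier recorded in the output table.
#' @return A data frame with one row per repeat: `protein_id`, `residue`,
#'   `start`, `end` (0-based, half-open), `length`. Repeats are reported in
#'   left-to-right order and are non-overlapping.
#' @examples
#' detect_aars("QQQQQSTWQQQQAAE")
#' @export
detect_aars <- function(sequence, min_len = 4L, protein_id = NA_character_) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  if (nchar(sequence) == 0L) stop("empty sequence")
  if (min_len < 1L) stop("min_len must be >= 1")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)            # 1-based inclusive end == 0-based exclusive end
  starts <- ends - r$lengths           # 0-based start
  keep <- r$lengths >= min_len & r$values %in% AA_STANDARD
  if (!any(keep)) return(empty_aar_table())
  data.frame(protein_id = protein_id,
             residue = r$values[keep],
             start = as.integer(starts[keep]),
             end = as.integer(ends[keep]),
             length = as.integer(r$lengths[keep]),
             stringsAsFactors = FALSE)
}

#' Repeat content in repeated residues per kilo amino acids (RRPK)
#'
#' RRPK is the total length of all repeats divided by the protein length,
#' multiplied by 1000. The 15-residue peptide `QQQQQSTWQQQQAAE` carries
#' 9 repeated residues, so its RRPK is 9/15 x 1000 = 600.
#'
#' @param sequence_length Protein (or segment) length in residues.
#' @param aars Repeat table as returned by [detect_aars()].
#' @return RRPK, a value in \[0, 1000\].
#' @export
compute_rrpk <- function(sequence_length, aars) {
  stopifnot(is.numeric(sequence_length), length(sequence_length) == 1L)
  if (sequence_length <= 0) stop("sequence_length must be positive")
  if (nrow(aars) == 0L) return(0)
  if (any(aars$start < 0L) || any(aars$end > sequence_length))
    stop("repeat coordinates outside [0, sequence_length)")
  1000 * sum(aars$end - aars$start) / sequence_length
}

#' GC content of a coding sequence
#'
#' Fraction of unambiguous bases that are G or C. IUPAC ambiguity codes
#' (including N) are excluded from both numerator and denominator; gaps and
#' U are tolerated and likewise excluded (U is first mapped to T).
#'
#' @param cds Character vector of nucleotide strings.
#' @return Numeric vector in \[0, 1\]; `NA` where a sequence has no
#'   unambiguous A/C/G/T base.
#' @export
gc_content <- function(cds) {
  stopifnot(is.character(cds))
  if (any(!is.na(cds) & nchar(cds) == 0L)) stop("empty coding sequence")
  x <- chartr("acgtu", "ACGTT", cds)
  gc <- nchar(gsub("[^GC]", "", x))
  at <- nchar(gsub("[^AT]", "", x))
  denom <- gc + at
  ifelse(denom > 0L, gc / denom, NA_real_)
}

# Segment boundaries for an equal split into n_regions parts.
# For length n = kq + r the remainder goes to the N-terminal-most segments
# (sizes q+1 for the first r), so the fixed convention is explicit when the
# N-terminal accumulation of repeats is assessed. Returns 0-based half-open
# boundaries of length n_regions + 1.
region_boundaries <- function(n, n_regions = 3L) {
  q <- n %/% n_regions
  r <- n %% n_regions
  sizes <- rep(q, n_regions) + c(rep(1L, r), rep(0L, n_regions - r))
  cumsum(c(0L, sizes))
}

#' Regional repeat and GC profile (protein thirds)
#'
#' Splits a protein into `n_regions` near-equal parts (remainder residues
#' assigned N-terminus first) and computes RRPK per region. A repeat that
#' spans a boundary contributes its residues to each region it overlaps, so
#' the region-weighted RRPK sum reproduces the total repeat residue count
#' exactly. When a coding sequence is present, regional GC is computed over
#' the codons of the residues in each region.
#'
#' @param sequence Amino-acid string.
#' @param aars Repeat table for the protein ([detect_aars()]).
#' @param cds Optional coding sequence (length 3x or 3x+3 of the protein).
#' @param n_regions Number of segments (default 3).
#' @return One-row data frame with `rrpk_1..rrpk_k`, `gc_1..gc_k` and
#'   segment lengths `len_1..len_k`.
#' @export
regional_profile <- function(sequence, aars, cds = NULL, n_regions = 3L) {
  n <- nchar(sequence)
  if (n < n_regions) stop("sequence shorter than the number of regions")
  b <- region_boundaries(n, n_regions)
  rrpk <- numeric(n_regions)
  gc <- rep(NA_real_, n_regions)
  for (k in seq_len(n_regions)) {
    lo <- b[k]; hi <- b[k + 1L]
    rep_res <- 0L
    if (nrow(aars) > 0L)
      rep_res <- sum(pmax(0L, pmin(aars$end, hi) - pmax(aars$start, lo)))
    rrpk[k] <- 1000 * rep_res / (hi - lo)
    if (!is.null(cds))
      gc[k] <- gc_content(substr(cds, 3L * lo + 1L, 3L * hi))
  }
  out <- as.data.frame(c(as.list(rrpk), as.list(gc), as.list(diff(b))))
  names(out) <- c(paste0("rrpk_", seq_len(n_regions)),
                  paste0("gc_", seq_len(n_regions)),
                  paste0("len_", seq_len(n_regions)))
  out
}

#' Residue composition inside repeats versus the whole protein set
#'
#' @param aars Combined repeat table over a protein set.
#' @param proteins Protein table with columns `id` and `sequence`.
#' @return Data frame with one row per standard amino acid: `residue`,
#'   `repeat_fraction` (fraction of all repeat residues that are this amino
#'   acid; `NA` if the set has no repeats), `background_fraction` (fraction
#'   over all standard residues of all proteins). Both columns sum to 1.
#' @export
aar_residue_composition <- function(aars, proteins) {
  stopifnot(nrow(proteins) > 0L)
  all_chars <- unlist(strsplit(proteins$sequence, "", fixed = TRUE), use.names = FALSE)
  bg <- table(factor(all_chars, levels = AA_STANDARD))
  bg_frac <- as.numeric(bg) / sum(bg)
  if (nrow(aars) > 0L) {
    rep_counts <- tapply(aars$end - aars$start,
                         factor(aars$residue, levels = AA_STANDARD), sum)
    rep_counts[is.na(rep_counts)] <- 0
    rep_frac <- as.numeric(rep_counts) / sum(rep_counts)
  } else {
    rep_frac <- rep(NA_real_, length(AA_STANDARD))
  }
  data.frame(residue = AA_STANDARD, repeat_fraction = rep_frac,
             background_fraction = bg_frac, stringsAsFactors = FALSE)
}

#' Is a repeat encoded by GC-rich codons?
#'
#' Alanine, glycine and proline are encoded by GC-rich codons; repeats of
#' these residues track coding GC content directly.
#'
#' @param residue Character vector of one-letter amino-acid codes.
#' @return Logical vector.
#' @export
classify_gc_rich <- function(residue) {
  residue %in% GC_RICH_RESIDUES
}

#' Scan a protein set for repeats and per-protein repeat profiles
#'
#' @param proteins Data frame with columns `id`, `sequence`, and optionally
#'   `species` and `cds`.
#' @param min_len Minimum repeat length (default 4).
#' @return A list with `aars` (combined repeat table, plus `gc_rich` flag)
#'   and `profiles` (per protein: `protein_id`, `species`, `length`,
#'   `n_aars`, `total_repeat_len`, `rrpk`, `gc`, `is_rcp`). A protein is a
#'   repeat-containing protein (RCP) iff it has at least one repeat.
#' @export
scan_proteins <- function(proteins, min_len = 4L) {
  stopifnot(is.data.frame(proteins), nrow(proteins) > 0L,
            all(c("id", "sequence") %in% names(proteins)))
  species <- if ("species" %in% names(proteins)) proteins$species else NA_character_
  cds <- if ("cds" %in% names(proteins)) proteins$cds else rep(NA_character_, nrow(proteins))
  aar_list <- lapply(seq_len(nrow(proteins)), function(i)
    detect_aars(proteins$sequence[i], min_len, proteins$id[i]))
  n_aars <- vapply(aar_list, nrow, integer(1))
  tot <- vapply(aar_list, function(a) sum(a$length), numeric(1))
  len <- nchar(proteins$sequence)
  aars <- do.call(rbind, aar_list)
  if (is.null(aars) || nrow(aars) == 0L) aars <- empty_aar_table()
  aars$gc_rich <- classify_gc_rich(aars$residue)
  profiles <- data.frame(protein_id = proteins$id,
                         species = species,
                         length = len,
                         n_aars = n_aars,
                         total_repeat_len = as.integer(tot),
                         rrpk = 1000 * tot / len,
                         gc = ifelse(is.na(cds), NA_real_, gc_content(ifelse(is.na(cds), "A", cds))),
                         is_rcp = n_aars > 0L,
                         stringsAsFactors = FALSE)
  list(aars = aars, profiles = profiles)
}

#' Per-species summary of repeat content
#'
#' @param profiles Per-protein profile table from [scan_proteins()].
#' @return Data frame per species: `n_proteins`, `mean_rrpk` (unweighted
#'   mean of per-protein RRPK), `mean_gc`, `aars_per_protein`
#'   (total repeat count / protein count), `rcp_fraction`.
#' @export
species_summary <- function(profiles) {
  stopifnot(nrow(profiles) > 0L)
  sp <- factor(profiles$species, levels = unique(profiles$species))
  agg <- function(x, f) as.numeric(tapply(x, sp, f))
  data.frame(species = levels(sp),
             n_proteins = as.integer(table(sp)),
             mean_rrpk = agg(profiles$rrpk, mean),
             mean_gc = agg(profiles$gc, function(x) mean(x, na.rm = TRUE)),
             aars_per_protein = agg(profiles$n_aars, mean),
             rcp_fraction = agg(profiles$is_rcp, mean),
             stringsAsFactors = FALSE)
}
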