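# Structural disorder of repeats: per-residue binary annotations are
# consumed as input (e.g. produced by an external disorder predictor at its
# default threshold); a repeat is fully disordered when every one of its
# residues is called disordered.

# Internal index of annotations for O(1) window queries: concatenated 0/1
# calls with per-protein offsets and a global prefix sum.
disorder_index <- function(annotations) {
  stopifnot(all(c("protein_id", "calls") %in% names(annotations)))
  if (any(grepl("[^01]", annotations$calls)))
    stop("disorder calls must be strings over {0,1}")
  lens <- nchar(annotations$calls)
  bits <- as.integer(unlist(strsplit(annotations$calls, "", fixed = TRUE),
                            use.names = FALSE))
  offsets <- cumsum(c(0L, lens))[seq_along(lens)]
  list(prefix = c(0L, cumsum(bits)),
       offset = stats::setNames(offsets, annotations$protein_id),
       length = stats::setNames(lens, annotations$protein_id))
}

# Sum of calls over [start, end) windows; `pid` vectorised with start/end.
window_sums <- function(idx, pid, start, end) {
  off <- idx$offset[pid]
  idx$prefix[off + end + 1L] - idx$prefix[off + start + 1L]
}

#' Is a repeat fully disordered?
#'
#' @param aar One row of a repeat table.
#' @param annotations Data frame with `protein_id` and `calls` (binary
#'   string, 1 = disordered residue), covering the repeat's protein.
#' @return TRUE iff every residue of the repeat is called disordered.
#' @export
is_fully_disordered <- function(aar, annotations) {
  idx <- disorder_index(annotations)
  if (!(aar$protein_id %in% names(idx$offset)))
    stop("no annotation for protein ", aar$protein_id)
  if (aar$end > idx$length[[aar$protein_id]])
    stop("repeat extends beyond the annotation for ", aar$protein_id)
  window_sums(idx, aar$protein_id, aar$start, aar$end) == (aar$end - aar$start)
}

#' Fraction of fully disordered repeats
#'
#' @param aars Repeat table.
#' @param annotations Annotation table covering every repeat's protein.
#' @return Fraction in \[0, 1\]; `NA` if the repeat table is empty.
#' @export
fully_disordered_fraction <- function(aars, annotations) {
  if (nrow(aars) == 0L) return(NA_real_)
  idx <- disorder_index(annotations)
  missing <- setdiff(aars$protein_id, names(idx$offset))
  if (length(missing) > 0L)
    stop("unannotated proteins: ", paste(utils::head(missing, 3), collapse = ", "))
  s <- window_sums(idx, aars$protein_id, aars$start, aars$end)
  mean(s == (aars$end - aars$start))
}

#' Random-segment permutation null for disorder enrichment in repeats
#'
#' For each of `n_trials` trials and each observed repeat, one segment of
#' the same length is drawn uniformly from the repeat-containing proteins
#' (pooled mode: protein chosen uniformly among RCPs long enough to hold
#' the segment, start uniform among valid positions; same-protein mode:
#' drawn from the repeat's own protein). The trial statistic is the
#' fraction of drawn segments that are fully disordered; the empirical
#' p-value is (b + 1)/(n_trials + 1) where b counts trials whose fraction
#' reaches or exceeds the observed fully-disordered fraction. Observing no
#' exceedance in 1000 trials therefore yields p = 1/1001 < 0.001.
#'
#' @param aars Repeat table (the observed repeats).
#' @param rcp_proteins Data frame of repeat-containing proteins with
#'   columns `id` and `length` (or `sequence`).
#' @param annotations Annotation table covering all RCPs.
#' @param n_trials Number of permutation trials (default 1000).
#' @param seed Integer seed; the whole null distribution is reproducible.
#' @param mode `"pooled"` (default) or `"same_protein"`.
#' @return A list of class `disorder_test`: `observed_fraction`,
#'   `null_fractions`, `empirical_p`, `n_trials`, `n_aars`, `seed`, `mode`.
#' @export
random_segment_null <- function(aars, rcp_proteins, annotations,
                                n_trials = 1000L, seed,
                                mode = c("pooled", "same_protein")) {
  mode <- match.arg(mode)
  stopifnot(n_trials >= 1L, nrow(aars) > 0L, nrow(rcp_proteins) > 0L)
  if (missing(seed)) stop("a seed is required for the permutation null")
  lens <- if ("length" %in% names(rcp_proteins)) rcp_proteins$length else
    nchar(rcp_proteins$sequence)
  idx <- disorder_index(annotations)
  observed <- fully_disordered_fraction(aars, annotations)
  m <- nrow(aars)
  seg_len <- aars$end - aars$start
  if (any(seg_len > max(lens)))
    stop("a repeat is longer than every RCP protein")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  disordered <- matrix(FALSE, nrow = m, ncol = n_trials)
  for (i in seq_len(m)) {
    L <- seg_len[i]
    if (mode == "same_protein") {
      pid <- rep(aars$protein_id[i], n_trials)
      plen <- rep(idx$length[[aars$protein_id[i]]], n_trials)
      if (plen[1] < L) stop("repeat longer than its own protein annotation")
    } else {
      eligible <- which(lens >= L)
      pick <- eligible[sample.int(length(eligible), n_trials, replace = TRUE)]
      pid <- rcp_proteins$id[pick]
      plen <- lens[pick]
    }
    start <- floor(stats::runif(n_trials) * (plen - L + 1))
    disordered[i, ] <- window_sums(idx, pid, start, start + L) == L
  }
  null_fractions <- colMeans(disordered)
  structure(list(observed_fraction = observed,
                 null_fractions = null_fractions,
                 empirical_p = empirical_p(observed, null_fractions, "ge"),
                 n_trials = n_trials, n_aars = m, seed = seed, mode = mode),
            class = "disorder_test")
}

#' @export
print.disorder_test <- function(x, ...) {
  cat("Random-segment permutation test (", x$mode, ", ", x$n_trials,
      " trials, seed ", x$seed, ")\n", sep = "")
  cat("  observed fully-disordered fraction:", format(x$observed_fraction), "\n")
  cat("  empirical p:", format(x$empirical_p), "\n")
  invisible(x)
}
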