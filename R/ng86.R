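# Nei-Gojobori (1986) codon-counting dN/dS with Jukes-Cantor correction.
#
# Site counting: at each codon position the unit site is split between
# synonymous and nonsynonymous in proportion to the fraction of single-base
# changes at that position that are synonymous, computed over non-stop
# alternatives only (renormalised, so every codon contributes exactly 3
# sites and N + S equals 3 x the number of compared codons).
#
# Difference counting: codon pairs differing at several positions are scored
# by averaging synonymous/nonsynonymous step counts over all orderings of
# the single-base changes; orderings passing through a stop codon are
# discarded (all orderings are used if every one is blocked).
#
# All per-codon and per-codon-pair quantities are precomputed once into
# lookup tables, so scoring a pair of sequences is a vectorised table sum.

ng86_env <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(ng86_env$codons)) return(ng86_env)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- unname(gc)
  is_stop <- aa == "*"
  bases <- c("A", "C", "G", "T")
  cmat <- do.call(rbind, strsplit(codons, ""))  # 64 x 3

  # fractional synonymous sites per codon (stops get NA)
  syn_sites <- rep(NA_real_, 64)
  for (i in which(!is_stop)) {
    s <- 0
    for (pos in 1:3) {
      alts <- bases[bases != cmat[i, pos]]
      alt_codons <- vapply(alts, function(b) {
        cc <- cmat[i, ]; cc[pos] <- b; paste(cc, collapse = "")
      }, character(1))
      alt_aa <- gc[alt_codons]
      valid <- alt_aa != "*"
      if (any(valid)) s <- s + sum(alt_aa[valid] == aa[i]) / sum(valid)
    }
    syn_sites[i] <- s
  }

  # pathway-averaged synonymous / nonsynonymous differences per codon pair
  perms <- list(`1` = matrix(1L, 1), `2` = rbind(c(1L, 2L), c(2L, 1L)),
                `3` = rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                            c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  sd_mat <- matrix(0, 64, 64, dimnames = list(codons, codons))
  nd_mat <- matrix(0, 64, 64, dimnames = list(codons, codons))
  for (i in which(!is_stop)) for (j in which(!is_stop)) {
    if (j <= i) next
    diffpos <- which(cmat[i, ] != cmat[j, ])
    nd_ <- length(diffpos)
    if (nd_ == 0L) next
    pm <- perms[[as.character(nd_)]]
    score <- function(order_idx, allow_stop) {
      cur <- cmat[i, ]; s <- 0; n <- 0
      for (p in diffpos[order_idx]) {
        aa_from <- gc[paste(cur, collapse = "")]
        cur[p] <- cmat[j, p]
        aa_to <- gc[paste(cur, collapse = "")]
        if (aa_to == "*" && !allow_stop) return(NULL)
        if (aa_to == aa_from) s <- s + 1 else n <- n + 1
      }
      c(s, n)
    }
    paths <- lapply(seq_len(nrow(pm)), function(k) score(pm[k, ], FALSE))
    paths <- paths[!vapply(paths, is.null, logical(1))]
    if (length(paths) == 0L)
      paths <- lapply(seq_len(nrow(pm)), function(k) score(pm[k, ], TRUE))
    avg <- Reduce(`+`, paths) / length(paths)
    sd_mat[i, j] <- sd_mat[j, i] <- avg[1]
    nd_mat[i, j] <- nd_mat[j, i] <- avg[2]
  }

  ng86_env$codons <- codons
  ng86_env$aa <- aa
  ng86_env$is_stop <- is_stop
  ng86_env$syn_sites <- syn_sites
  ng86_env$sd_mat <- sd_mat
  ng86_env$nd_mat <- nd_mat
  ng86_env
}

split_codons <- function(x) {
  n <- nchar(x)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) counting method
#'
#' Counts fractional synonymous/nonsynonymous sites (averaged over both
#' sequences), pathway-averaged differences, and applies the Jukes-Cantor
#' correction d = -(3/4) ln(1 - (4/3) p) to both proportions. Codon pairs in
#' which either member carries a gap, an ambiguity code or a stop codon are
#' excluded listwise.
#'
#' @param codons_a,codons_b Nucleotide strings of equal length divisible
#'   by 3 (aligned, ungapped after filtering).
#' @return A list of class `ng86_dnds`: `dn`, `ds`, `ratio`, `n_sites`,
#'   `s_sites`, `nd`, `sd`, `pn`, `ps`, `n_codons_used`, and a `flag`
#'   (`"ok"`, `"undefined"` for 0/0, `"infinite"` for dn > 0 with ds = 0,
#'   `"saturated"` when a proportion reaches the Jukes-Cantor limit 3/4,
#'   `"empty"` when no codon pair survives filtering).
#' @export
ng86_dnds <- function(codons_a, codons_b) {
  stopifnot(is.character(codons_a), is.character(codons_b),
            length(codons_a) == 1L, length(codons_b) == 1L)
  if (nchar(codons_a) != nchar(codons_b)) stop("sequences differ in length")
  tb <- ng86_tables()
  ca <- split_codons(toupper(codons_a))
  cb <- split_codons(toupper(codons_b))
  ia <- match(ca, tb$codons)
  ib <- match(cb, tb$codons)
  keep <- !is.na(ia) & !is.na(ib) & !tb$is_stop[ifelse(is.na(ia), 1L, ia)] &
    !tb$is_stop[ifelse(is.na(ib), 1L, ib)]
  ia <- ia[keep]; ib <- ib[keep]
  out <- list(dn = NA_real_, ds = NA_real_, ratio = NA_real_,
              n_sites = NA_real_, s_sites = NA_real_,
              nd = NA_real_, sd = NA_real_, pn = NA_real_, ps = NA_real_,
              n_codons_used = length(ia), flag = "empty")
  class(out) <- "ng86_dnds"
  if (length(ia) == 0L) return(out)
  S <- (sum(tb$syn_sites[ia]) + sum(tb$syn_sites[ib])) / 2
  Nsites <- 3 * length(ia) - S
  sd_ <- sum(tb$sd_mat[cbind(ia, ib)])
  nd_ <- sum(tb$nd_mat[cbind(ia, ib)])
  ps <- if (S > 0) sd_ / S else 0
  pn <- if (Nsites > 0) nd_ / Nsites else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ds <- jc(ps); dn <- jc(pn)
  out$n_sites <- Nsites; out$s_sites <- S
  out$sd <- sd_; out$nd <- nd_; out$ps <- ps; out$pn <- pn
  out$ds <- ds; out$dn <- dn
  if (is.na(ds) || is.na(dn)) {
    out$flag <- "saturated"
  } else if (ds > 0) {
    out$ratio <- dn / ds
    out$flag <- "ok"
  } else if (dn > 0) {
    out$ratio <- Inf
    out$flag <- "infinite"
  } else {
    out$flag <- "undefined"
  }
  out
}

#' @export
print.ng86_dnds <- function(x, ...) {
  cat("NG86 dN/dS:", format(x$ratio), " (dN =", format(x$dn),
      ", dS =", format(x$ds), ",", x$n_codons_used, "codons,",
      x$flag, ")\n")
  invisible(x)
}
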