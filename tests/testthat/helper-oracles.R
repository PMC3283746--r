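# Independent oracles used across the suite. Each re-derives the quantity
# by a different route (enumeration, direct summation, or closed form) than
# the implementation under test.

STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# --- repeat detection: per-position extension scan -------------------------
oracle_detect_runs <- function(sequence, min_len = 4L) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  out <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && chars[j + 1L] == chars[i]) j <- j + 1L
    if (j - i + 1L >= min_len && chars[i] %in% STANDARD_AA)
      out[[length(out) + 1L]] <- data.frame(residue = chars[i],
                                            start = i - 1L, end = j,
                                            stringsAsFactors = FALSE)
    i <- j + 1L
  }
  if (length(out) == 0L)
    return(data.frame(residue = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

random_protein <- function(n, alphabet = STANDARD_AA, prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

# repeat-enriched sampler: random runs pasted between random stretches
repeat_enriched_protein <- function(n) {
  parts <- character(0)
  len <- 0L
  while (len < n) {
    if (runif(1) < 0.4) {
      k <- sample(2:9, 1L)
      parts <- c(parts, strrep(sample(STANDARD_AA, 1L), k))
    } else {
      k <- sample(1:12, 1L)
      parts <- c(parts, random_protein(k))
    }
    len <- len + k
  }
  substr(paste(parts, collapse = ""), 1L, n)
}

# --- NG86: per-codon site and per-pair pathway enumeration -----------------
GENCODE <- Biostrings::GENETIC_CODE
BASES <- c("A", "C", "G", "T")
SENSE_CODONS <- names(GENCODE)[GENCODE != "*"]

oracle_codon_sites <- function(codon) {
  aa <- GENCODE[[codon]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; valid <- 0L
    for (b in setdiff(BASES, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (GENCODE[[alt]] == "*") next
      valid <- valid + 1L
      if (GENCODE[[alt]] == aa) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  c(syn_sites = s, nonsyn_sites = 3 - s)
}

oracle_codon_diffs <- function(c1, c2) {
  diffpos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  if (length(diffpos) == 0L) return(c(sd = 0, nd = 0))
  orders <- if (length(diffpos) == 1L) list(diffpos) else
    asplit(do.call(rbind, lapply(combinat_perms(length(diffpos)),
                                 function(p) diffpos[p])), 1L)
  paths <- list()
  for (ord in orders) {
    cur <- c1; s <- 0L; n <- 0L; blocked <- FALSE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (GENCODE[[nxt]] == "*") { blocked <- TRUE; break }
      if (GENCODE[[nxt]] == GENCODE[[cur]]) s <- s + 1L else n <- n + 1L
      cur <- nxt
    }
    if (!blocked) paths[[length(paths) + 1L]] <- c(s, n)
  }
  if (length(paths) == 0L) {  # all orderings pass through a stop
    for (ord in orders) {
      cur <- c1; s <- 0L; n <- 0L
      for (pos in ord) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (GENCODE[[nxt]] == GENCODE[[cur]]) s <- s + 1L else n <- n + 1L
        cur <- nxt
      }
      paths[[length(paths) + 1L]] <- c(s, n)
    }
  }
  avg <- Reduce(`+`, paths) / length(paths)
  c(sd = avg[1], nd = avg[2])
}

combinat_perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) for (p in combinat_perms(k - 1L)) {
    rest <- setdiff(seq_len(k), i)
    out[[length(out) + 1L]] <- c(i, rest[p])
  }
  out
}

# neutral codon-pair simulator: each branch mutates each nucleotide with
# probability p_site to a uniform different base, rejecting mutations that
# create a stop codon (mirroring the estimator's stop-excluded site space)
sim_neutral_pair <- function(n_codons, p_site = 0.05) {
  anc <- sample(SENSE_CODONS, n_codons, replace = TRUE)
  branch <- function(codons) {
    for (i in seq_along(codons)) {
      cod <- codons[i]
      for (pos in 1:3) {
        if (runif(1) >= p_site) next
        nxt <- cod
        substr(nxt, pos, pos) <- sample(setdiff(BASES, substr(cod, pos, pos)), 1L)
        if (GENCODE[[nxt]] != "*") cod <- nxt
      }
      codons[i] <- cod
    }
    codons
  }
  list(a = paste(branch(anc), collapse = ""),
       b = paste(branch(anc), collapse = ""))
}

# --- Fisher 2x2: direct log-choose summation -------------------------------
oracle_fisher_p <- function(tab) {
  x <- tab[1, 1]; m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0L, k - n); hi <- min(k, m)
  supp <- lo:hi
  logp <- lchoose(m, supp) + lchoose(n, k - supp) - lchoose(m + n, k)
  p <- exp(logp)
  sum(p[p <= p[x - lo + 1L] * (1 + 1e-7)])
}

# --- Mann-Whitney exact p by enumeration of rank assignments ---------------
oracle_mw_exact_p <- function(a, b) {
  n1 <- length(a); N <- n1 + length(b)
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(N, n1)
  u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(u_all <= U_obs), mean(u_all >= U_obs)))
}

# --- Grubbs p by root-finding the critical-value relation ------------------
oracle_grubbs_p <- function(G, N) {
  gcrit <- function(alpha) {
    t <- stats::qt(1 - alpha / (2 * N), N - 2)
    (N - 1) / sqrt(N) * sqrt(t^2 / (N - 2 + t^2))
  }
  if (G >= gcrit(1e-12)) return(0)
  if (G <= gcrit(1)) return(1)
  stats::uniroot(function(a) gcrit(a) - G, c(1e-12, 1), tol = 1e-12)$root
}

# --- small ortholog-group builder ------------------------------------------
# Builds a group from aligned AA rows by assigning an arbitrary valid codon
# to every residue (deterministic: first codon of the amino acid).
toy_group <- function(rows, species = NULL, group_id = "g1") {
  ids <- names(rows)
  if (is.null(species)) species <- paste0("sp", seq_along(rows))
  first_codon <- vapply(split(SENSE_CODONS, GENCODE[SENSE_CODONS]),
                        `[`, "", 1L)
  cds <- vapply(rows, function(r) {
    aa <- strsplit(gsub("-", "", r), "")[[1L]]
    paste(first_codon[aa], collapse = "")
  }, character(1))
  ortholog_group(group_id,
                 data.frame(id = ids, species = species,
                            stringsAsFactors = FALSE),
                 rows, cds)
}
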