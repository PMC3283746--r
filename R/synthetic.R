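# Seeded synthetic-data generator. Produces orthologous protein/CDS bundles
# whose statistical structure matches what the analysis assumes: repeat
# (homopolymer) tracts whose expected total length rises linearly with
# coding GC content, ortholog groups containing both conserved and
# lineage-specific tracts (a star phylogeny with indels confined to tracts,
# so the multiple alignment is exact by construction), per-residue disorder
# calls enriched in and around tracts, log-normal tissue expression,
# exponential mRNA half-lives with a configurable repeat-protein effect,
# multi-model gene structures, and gene/hotspot intervals.

# Background amino-acid frequencies for non-repeat positions (rough
# eukaryotic proteome composition).
BG_AA_FREQ <- c(A = 0.08, C = 0.02, D = 0.054, E = 0.067, F = 0.039,
                G = 0.066, H = 0.023, I = 0.053, K = 0.058, L = 0.096,
                M = 0.024, N = 0.041, P = 0.048, Q = 0.040, R = 0.055,
                S = 0.081, T = 0.053, V = 0.068, W = 0.011, Y = 0.029)

codon_env <- new.env(parent = emptyenv())

codon_sets <- function() {
  if (!is.null(codon_env$by_aa)) return(codon_env)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  aa <- unname(gc[gc != "*"])
  ngc <- nchar(gsub("[^GC]", "", codons))
  codon_env$by_aa <- split(codons, aa)
  codon_env$ngc_by_aa <- split(ngc, aa)
  codon_env
}

# Sample one codon per amino acid in `aa_chars`, with GC preference
# theta: codon weight proportional to exp(theta * n_GC_bases).
sample_codons <- function(aa_chars, theta) {
  cs <- codon_sets()
  out <- character(length(aa_chars))
  for (a in unique(aa_chars)) {
    idx <- which(aa_chars == a)
    set <- cs$by_aa[[a]]
    if (length(set) == 1L) {
      out[idx] <- set
    } else {
      w <- exp(theta * cs$ngc_by_aa[[a]])
      out[idx] <- set[sample.int(length(set), length(idx), replace = TRUE,
                                 prob = w)]
    }
  }
  out
}

#' Configuration for the synthetic-data generator
#'
#' `base_repeat_residues` and `slippage_gc_coupling` set the repeat-GC
#' coupling: the expected number of seeded repeat residues per protein in a
#' species with GC target g is approximately `base + coupling * g`
#' (approximate because tract counts are capped in short proteins). The
#' defaults are sized for desk-scale experiments (tens of ortholog groups):
#' the coupling is deliberately strong so the RRPK-GC correlation is
#' detectable across 10 species with ~80 proteins each.
#'
#' @param seed Integer seed; identical seed + config gives an identical
#'   bundle.
#' @param n_species,n_groups Number of species and of 1-to-1 ortholog
#'   groups (one protein per species per group).
#' @param protein_length_range Backbone length range (residues), before
#'   tract insertion.
#' @param gc_targets Per-species coding GC targets in (0,1).
#' @param base_repeat_residues,slippage_gc_coupling Linear coupling of
#'   expected seeded repeat residues per protein to species GC.
#' @param tract_rate Mean number of seeded tract sites per group (Poisson,
#'   capped by protein length).
#' @param conserved_repeat_prob Probability a tract site is conserved:
#'   present in every species at a fixed length of at least 8.
#' @param tract_presence_prob Probability a non-conserved tract is present
#'   in a given species (lineage specificity).
#' @param tract_max_len Cap on realised tract length.
#' @param repeat_residue_weights Sampling weights of tract residues.
#' @param syn_sub_prob Per-codon probability of a synonymous codon
#'   resampling on each species branch (also carries the species GC bias).
#' @param nonsyn_sub_prob Per-codon probability of an amino-acid
#'   substitution on each species branch, outside flanks.
#' @param flank_relaxation Multiplier on `nonsyn_sub_prob` within
#'   `flank_len` residues of a tract (>= 1; 1 = no relaxation).
#' @param flank_len Flank window in residues (default 33).
#' @param disorder_in_repeat_p,disorder_background_p Named length-2 vectors
#'   (two pseudo-tracks) of per-residue disorder probabilities inside
#'   tracts +/- `disorder_window` residues, and elsewhere.
#' @param disorder_window Residues around a tract that share the in-repeat
#'   disorder probability.
#' @param n_tissues Number of expression tissues.
#' @param tissue_specific_frac_rcp,tissue_specific_frac_nonrcp Fractions of
#'   repeat-containing / repeat-free genes with single-tissue expression.
#' @param halflife_mean_hours Mean mRNA half-life of repeat-free genes.
#' @param rcp_halflife_factor Multiplier on the mean half-life of
#'   repeat-containing genes (< 1 = faster decay).
#' @param alt_splice_prob Probability a multi-exon gene has a second model.
#' @param n_hotspots Number of recombination hotspot intervals.
#' @param rcp_hotspot_boost Relative odds that a hotspot is anchored on a
#'   repeat-containing gene.
#' @return A list of class `aar_generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_species = 10L,
                             n_groups = 80L,
                             protein_length_range = c(100L, 200L),
                             gc_targets = seq(0.40, 0.62, length.out = n_species),
                             base_repeat_residues = 2,
                             slippage_gc_coupling = 50,
                             tract_rate = 2,
                             conserved_repeat_prob = 0.1,
                             tract_presence_prob = 0.6,
                             tract_max_len = 34L,
                             repeat_residue_weights = c(S = 0.20, A = 0.12,
                                                        G = 0.12, P = 0.10,
                                                        Q = 0.14, E = 0.12,
                                                        K = 0.06, L = 0.06,
                                                        D = 0.04, R = 0.04),
                             syn_sub_prob = 0.18,
                             nonsyn_sub_prob = 0.06,
                             flank_relaxation = 3,
                             flank_len = 33L,
                             disorder_in_repeat_p = c(vsl2b_like = 0.95,
                                                      iupred_like = 0.75),
                             disorder_background_p = c(vsl2b_like = 0.35,
                                                       iupred_like = 0.15),
                             disorder_window = 10L,
                             n_tissues = 8L,
                             tissue_specific_frac_rcp = 0.4,
                             tissue_specific_frac_nonrcp = 0.15,
                             halflife_mean_hours = 4,
                             rcp_halflife_factor = 0.7,
                             alt_splice_prob = 0.25,
                             n_hotspots = 40L,
                             rcp_hotspot_boost = 3) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$gc_targets) == cfg$n_species,
            all(cfg$gc_targets > 0 & cfg$gc_targets < 1),
            cfg$protein_length_range[1] >= 50L,
            cfg$protein_length_range[1] <= cfg$protein_length_range[2],
            cfg$slippage_gc_coupling >= 0, cfg$flank_relaxation >= 1,
            all(cfg$disorder_in_repeat_p >= 0 & cfg$disorder_in_repeat_p <= 1),
            all(cfg$disorder_background_p >= 0 & cfg$disorder_background_p <= 1),
            cfg$conserved_repeat_prob >= 0, cfg$conserved_repeat_prob <= 1,
            cfg$tract_presence_prob > 0, cfg$tract_presence_prob <= 1,
            cfg$n_tissues >= 2L, cfg$rcp_halflife_factor > 0,
            cfg$alt_splice_prob >= 0, cfg$alt_splice_prob <= 1)
  # feasibility of the repeat-residue coupling identity
  lam <- nonconserved_tract_mean(cfg, min(cfg$gc_targets))
  if (lam < 4)
    stop("infeasible config: base_repeat_residues/slippage_gc_coupling ",
         "imply a mean non-conserved tract length below the minimum ",
         "repeat length 4 at the lowest GC target (",
         format(lam), "); raise base_repeat_residues")
  structure(cfg, class = "aar_generator_config")
}

# Mean realised length of a non-conserved tract at species GC target g,
# solving E[repeat residues per protein] = base + coupling * g under the
# tract composition of the config.
nonconserved_tract_mean <- function(cfg, g) {
  target <- cfg$base_repeat_residues + cfg$slippage_gc_coupling * g
  cons_mean <- 10  # conserved tracts: 8 + Poisson(2)
  p_c <- cfg$conserved_repeat_prob
  (target / cfg$tract_rate - p_c * cons_mean) /
    ((1 - p_c) * cfg$tract_presence_prob)
}

# Bernoulli 0/1 string of length n with position-dependent probability.
bernoulli_calls <- function(p) paste(ifelse(stats::runif(length(p)) < p, "1", "0"),
                                     collapse = "")

#' Toy per-residue disorder annotator for synthetic proteins
#'
#' Emits Bernoulli disorder calls at the configured in-repeat probability
#' inside tract windows (tract +/- `disorder_window` residues) and at the
#' background probability elsewhere. A stand-in annotation source for the
#' synthetic bundle only; it does not predict disorder from sequence.
#'
#' @param protein_length Protein length.
#' @param tracts Data frame of the protein's true repeat tracts (`start`,
#'   `end`, 0-based half-open); may have zero rows.
#' @param p_in,p_bg In-window and background disorder probabilities.
#' @param window Residues around each tract sharing `p_in`.
#' @return Binary call string of length `protein_length`.
#' @export
toy_disorder_annotator <- function(protein_length, tracts, p_in, p_bg,
                                   window = 10L) {
  p <- rep(p_bg, protein_length)
  if (nrow(tracts) > 0L) for (i in seq_len(nrow(tracts))) {
    lo <- max(0L, tracts$start[i] - window)
    hi <- min(protein_length, tracts$end[i] + window)
    if (hi > lo) p[(lo + 1L):hi] <- p_in
  }
  bernoulli_calls(p)
}

# Reconcile a seeded tract with the realised sequence: extend while the
# neighbouring residues happen to equal the tract residue, so ground truth
# matches the maximal runs a scanner reports.
reconcile_tract <- function(chars, start, end, residue) {
  while (start > 0L && chars[start] == residue) start <- start - 1L
  n <- length(chars)
  while (end < n && chars[end + 1L] == residue) end <- end + 1L
  c(start, end)
}

#' Generate a synthetic analysis bundle
#'
#' Deterministic given `config$seed`. See [generator_config()] for the
#' generative model. The `parts` argument limits generation to what an
#' experiment needs: `"sequences"` (proteins + CDS + tract ground truth) is
#' always produced; `"alignments"` adds validated [ortholog_group()]
#' objects; `"disorder"` adds two annotation tracks; `"regulation"` adds
#' expression, half-lives, gene models and gene/hotspot intervals for the
#' first (focal) species.
#'
#' @param config An `aar_generator_config`.
#' @param parts Character subset of
#'   `c("sequences", "alignments", "disorder", "regulation")`.
#' @return A list of class `aar_bundle` with elements `config`, `species`
#'   (id + gc_target), `proteins` (id, species, group_id, sequence, cds,
#'   length, is_rcp), `truth_tracts`, and, per `parts`: `groups`,
#'   `disorder` (named list of annotation tables), `expression` (list:
#'   `raw`, `present`, `probe_map`), `half_lives`, `gene_models` (list:
#'   `models` genomic exon table, `exon_map` per-gene coding-exon lengths
#'   and classes), `genes_bed`, `hotspots_bed`.
#' @export
generate_bundle <- function(config,
                            parts = c("sequences", "alignments",
                                      "disorder", "regulation")) {
  stopifnot(inherits(config, "aar_generator_config"))
  parts <- match.arg(parts, several.ok = TRUE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(config$seed)

  n_sp <- config$n_species
  sp_ids <- sprintf("sp%02d", seq_len(n_sp))
  theta <- 4 * (config$gc_targets - 0.5)
  theta_anc <- 4 * (mean(config$gc_targets) - 0.5)
  lam_s <- pmax(0, vapply(config$gc_targets,
                          function(g) nonconserved_tract_mean(config, g),
                          numeric(1)) - 4)
  rw <- config$repeat_residue_weights
  aa_names <- names(BG_AA_FREQ)

  n_prot <- config$n_groups * n_sp
  p_id <- character(n_prot); p_sp <- character(n_prot)
  p_gid <- character(n_prot); p_seq <- character(n_prot)
  p_cds <- character(n_prot); p_rcp <- logical(n_prot)
  tr_chunks <- vector("list", n_prot)   # per-protein tract chunks
  groups <- if ("alignments" %in% parts) vector("list", config$n_groups) else NULL
  pi_ <- 0L
  p_ns <- config$nonsyn_sub_prob
  p_ns_flank <- p_ns * config$flank_relaxation

  for (g in seq_len(config$n_groups)) {
    gid <- sprintf("og%04d", g)
    L <- sample(config$protein_length_range[1]:config$protein_length_range[2], 1L)
    anc_aa <- sample(aa_names, L, replace = TRUE, prob = BG_AA_FREQ)
    anc_codons <- sample_codons(anc_aa, theta_anc)

    slot <- config$tract_max_len + 10L
    k_max <- max(0L, L %/% (slot + 10L))
    K <- min(stats::rpois(1L, config$tract_rate), k_max)
    td_anchor <- integer(0); td_res <- character(0)
    td_cons <- logical(0); td_conslen <- integer(0)
    if (K > 0L) {
      anchors <- sort(sample.int(L - slot, K))
      ok <- K == 1L || all(diff(anchors) >= slot)
      tries <- 0L
      while (!ok && tries < 50L) {
        anchors <- sort(sample.int(L - slot, K))
        ok <- all(diff(anchors) >= slot)
        tries <- tries + 1L
      }
      if (!ok) { K <- 1L; anchors <- anchors[1L] }
      td_anchor <- anchors
      td_res <- sample(names(rw), K, replace = TRUE, prob = rw)
      td_cons <- stats::runif(K) < config$conserved_repeat_prob
      td_conslen <- 8L + stats::rpois(K, 2)
    }

    # realised tract lengths per species (0 = absent)
    lens_mat <- matrix(0L, nrow = max(K, 0L), ncol = n_sp)
    if (K > 0L) for (tt in seq_len(K)) {
      if (td_cons[tt]) {
        lens_mat[tt, ] <- td_conslen[tt]
      } else {
        present <- stats::runif(n_sp) < config$tract_presence_prob
        ln <- 4L + stats::rpois(n_sp, lam_s)
        lens_mat[tt, ] <- ifelse(present, pmin(ln, config$tract_max_len), 0L)
      }
    }
    block_w <- if (K > 0L) apply(lens_mat, 1L, max) else integer(0)

    msa_rows <- character(n_sp)
    for (s in seq_len(n_sp)) {
      aa <- anc_aa
      codons <- anc_codons
      # flank mask on the backbone: within flank_len of a tract present here
      p_nonsyn <- rep(p_ns, L)
      if (K > 0L) for (tt in seq_len(K)) {
        if (lens_mat[tt, s] == 0L) next
        a <- td_anchor[tt]
        p_nonsyn[max(1L, a - config$flank_len + 1L):min(L, a + config$flank_len)] <- p_ns_flank
      }
      u <- stats::runif(L)
      ns_idx <- which(u < p_nonsyn)
      if (length(ns_idx) > 0L) {
        new_aa <- sample(aa_names, length(ns_idx), replace = TRUE, prob = BG_AA_FREQ)
        same <- new_aa == aa[ns_idx]
        while (any(same)) {
          new_aa[same] <- sample(aa_names, sum(same), replace = TRUE, prob = BG_AA_FREQ)
          same <- new_aa == aa[ns_idx]
        }
        aa[ns_idx] <- new_aa
        codons[ns_idx] <- sample_codons(new_aa, theta[s])
      }
      syn_idx <- which(u >= p_nonsyn & stats::runif(L) < config$syn_sub_prob)
      if (length(syn_idx) > 0L)
        codons[syn_idx] <- sample_codons(aa[syn_idx], theta[s])

      # assemble backbone segments and tract insertions
      pid <- paste0(sp_ids[s], "_", gid)
      n_parts <- 2L * K + 1L
      seq_parts <- character(n_parts); cds_parts <- character(n_parts)
      msa_parts <- character(n_parts)
      pos <- 0L          # residues emitted so far (species coordinates)
      prev_anchor <- 0L
      t_res <- character(K); t_start <- integer(K); t_end <- integer(K)
      t_cons <- logical(K); n_tr <- 0L
      if (K > 0L) for (tt in seq_len(K)) {
        a <- td_anchor[tt]
        seg <- if (a > prev_anchor) (prev_anchor + 1L):a else integer(0)
        seg_aa <- paste(aa[seg], collapse = "")
        seq_parts[2L * tt - 1L] <- seg_aa
        cds_parts[2L * tt - 1L] <- paste(codons[seg], collapse = "")
        pos <- pos + length(seg)
        ln <- lens_mat[tt, s]
        res <- td_res[tt]
        if (ln > 0L) {
          tract_aa <- strrep(res, ln)
          seq_parts[2L * tt] <- tract_aa
          cds_parts[2L * tt] <- paste(sample_codons(rep(res, ln), theta[s]),
                                      collapse = "")
          n_tr <- n_tr + 1L
          t_res[n_tr] <- res; t_start[n_tr] <- pos; t_end[n_tr] <- pos + ln
          t_cons[n_tr] <- td_cons[tt]
          pos <- pos + ln
        } else tract_aa <- ""
        msa_parts[2L * tt - 1L] <- seg_aa
        msa_parts[2L * tt] <- paste0(tract_aa, strrep("-", block_w[tt] - ln))
        prev_anchor <- a
      }
      seg <- if (L > prev_anchor) (prev_anchor + 1L):L else integer(0)
      seg_aa <- paste(aa[seg], collapse = "")
      seq_parts[n_parts] <- seg_aa
      cds_parts[n_parts] <- paste(codons[seg], collapse = "")
      msa_parts[n_parts] <- seg_aa

      pseq <- paste(seq_parts, collapse = "")
      msa_rows[s] <- paste(msa_parts, collapse = "")
      pi_ <- pi_ + 1L
      p_id[pi_] <- pid; p_sp[pi_] <- sp_ids[s]; p_gid[pi_] <- gid
      p_seq[pi_] <- pseq
      p_cds[pi_] <- paste(cds_parts, collapse = "")
      p_rcp[pi_] <- n_tr > 0L
      if (n_tr > 0L) {
        chars <- strsplit(pseq, "", fixed = TRUE)[[1L]]
        st <- t_start[seq_len(n_tr)]; en <- t_end[seq_len(n_tr)]
        for (i in seq_len(n_tr)) {
          se <- reconcile_tract(chars, st[i], en[i], t_res[i])
          st[i] <- se[1]; en[i] <- se[2]
        }
        tr_chunks[[pi_]] <- list(pid = pid, gid = gid, sp = sp_ids[s],
                                 res = t_res[seq_len(n_tr)], start = st,
                                 end = en, cons = t_cons[seq_len(n_tr)])
      }
    }
    if ("alignments" %in% parts) {
      ids_g <- p_id[(pi_ - n_sp + 1L):pi_]
      names(msa_rows) <- ids_g
      groups[[g]] <- ortholog_group(
        gid, data.frame(id = ids_g, species = sp_ids,
                        stringsAsFactors = FALSE),
        msa_rows,
        stats::setNames(p_cds[(pi_ - n_sp + 1L):pi_], ids_g))
    }
  }

  proteins <- data.frame(id = p_id, species = p_sp, group_id = p_gid,
                         sequence = p_seq, cds = p_cds,
                         length = nchar(p_seq), is_rcp = p_rcp,
                         stringsAsFactors = FALSE)
  tr_chunks <- tr_chunks[!vapply(tr_chunks, is.null, logical(1))]
  pull <- function(f, how = unlist)
    how(lapply(tr_chunks, function(ch) rep(ch[[f]], length.out = length(ch$res))))
  truth_tracts <- if (length(tr_chunks) > 0L)
    data.frame(protein_id = pull("pid"), group_id = pull("gid"),
               species = pull("sp"), residue = unlist(lapply(tr_chunks, `[[`, "res")),
               start = unlist(lapply(tr_chunks, `[[`, "start")),
               end = unlist(lapply(tr_chunks, `[[`, "end")),
               conserved = unlist(lapply(tr_chunks, `[[`, "cons")),
               stringsAsFactors = FALSE) else
    data.frame(protein_id = character(0), group_id = character(0),
               species = character(0), residue = character(0),
               start = integer(0), end = integer(0), conserved = logical(0),
               stringsAsFactors = FALSE)
  if ("alignments" %in% parts) names(groups) <- vapply(groups, `[[`, "", "group_id")

  bundle <- list(config = config,
                 species = data.frame(species = sp_ids,
                                      gc_target = config$gc_targets,
                                      stringsAsFactors = FALSE),
                 proteins = proteins, truth_tracts = truth_tracts)
  if ("alignments" %in% parts) bundle$groups <- groups

  if ("disorder" %in% parts) {
    tracks <- names(config$disorder_in_repeat_p)
    bundle$disorder <- lapply(stats::setNames(tracks, tracks), function(tr) {
      calls <- vapply(seq_len(nrow(proteins)), function(i) {
        tt <- truth_tracts[truth_tracts$protein_id == proteins$id[i], , drop = FALSE]
        toy_disorder_annotator(proteins$length[i], tt,
                               config$disorder_in_repeat_p[[tr]],
                               config$disorder_background_p[[tr]],
                               config$disorder_window)
      }, character(1))
      data.frame(protein_id = proteins$id, calls = calls,
                 stringsAsFactors = FALSE)
    })
  }

  if ("regulation" %in% parts)
    bundle <- c(bundle, synth_regulation(config, proteins, truth_tracts))
  structure(bundle, class = "aar_bundle")
}

# Regulation-layer outputs for the focal (first) species.
synth_regulation <- function(config, proteins, truth_tracts) {
  focal <- proteins[proteins$species == proteins$species[1], , drop = FALSE]
  n <- nrow(focal)
  gene <- focal$id
  is_rcp <- focal$is_rcp

  # probes: 1 or 2 per locus
  n_probes <- 1L + (stats::runif(n) < 0.3)
  probe_map <- data.frame(
    probe = paste0("probe_", sequence(n_probes), "_", rep(gene, n_probes)),
    locus = rep(gene, n_probes), stringsAsFactors = FALSE)

  # expression: log-normal; tissue-specific genes express in one tissue
  specific <- stats::runif(n) < ifelse(is_rcp, config$tissue_specific_frac_rcp,
                                       config$tissue_specific_frac_nonrcp)
  nt <- config$n_tissues
  raw <- matrix(NA_real_, nrow = sum(n_probes), ncol = nt,
                dimnames = list(probe_map$probe,
                                paste0("tissue_", seq_len(nt))))
  gi <- rep(seq_len(n), n_probes)
  for (r in seq_len(nrow(raw))) {
    i <- gi[r]
    mu <- stats::rnorm(1, 8, 1)
    lg <- stats::rnorm(nt, mu, 0.5)
    if (specific[i]) {
      hot <- sample.int(nt, 1L)
      lg <- lg - 3
      lg[hot] <- lg[hot] + 7
    }
    raw[r, ] <- 2^lg
  }
  present <- matrix(stats::runif(length(raw)) < 0.95, nrow(raw), ncol(raw),
                    dimnames = dimnames(raw))

  half_lives <- data.frame(
    probe = probe_map$probe,
    hours = stats::rexp(nrow(probe_map),
                        rate = 1 / (config$halflife_mean_hours *
                                      ifelse(is_rcp[gi], config$rcp_halflife_factor, 1))),
    stringsAsFactors = FALSE)

  # gene models along one chromosome; second models drop one exon,
  # preferentially a repeat-overlapping one
  models <- list(); exon_map <- list(); genes_bed <- list()
  cursor <- 1000L
  for (i in seq_len(n)) {
    cds_len <- 3L * focal$length[i]
    n_ex <- sample(1:4, 1L)
    if (n_ex > 1L) {
      cuts <- sort(sample(seq(9L, cds_len - 9L, by = 3L), n_ex - 1L))
      ex_len <- diff(c(0L, cuts, cds_len))
    } else ex_len <- cds_len
    introns <- if (n_ex > 1L) sample(50:500, n_ex - 1L, replace = TRUE) else integer(0)
    starts <- cursor + cumsum(c(0L, ex_len[-n_ex] + introns))
    ends <- starts + ex_len
    models[[length(models) + 1L]] <- data.frame(
      gene = gene[i], model = paste0(gene[i], ".1"),
      start = starts, end = ends, strand = "+", stringsAsFactors = FALSE)
    classes <- rep("constitutive", n_ex)
    if (n_ex >= 2L && stats::runif(1) < config$alt_splice_prob) {
      # dropped (alternative) exons are repeat-enriched: prefer an exon
      # whose residue span overlaps a true tract
      drop_candidates <- seq_len(n_ex)
      tr <- truth_tracts[truth_tracts$protein_id == gene[i], , drop = FALSE]
      if (nrow(tr) > 0L) {
        cum <- cumsum(c(0L, ex_len))
        res_lo <- cum[-(n_ex + 1L)] %/% 3L
        res_hi <- (cum[-1L] + 2L) %/% 3L
        overlaps <- vapply(seq_len(n_ex), function(e)
          any(tr$start < res_hi[e] & tr$end > res_lo[e]), logical(1))
        if (any(overlaps) && stats::runif(1) < 0.8)
          drop_candidates <- which(overlaps)
      }
      drop <- if (length(drop_candidates) == 1L) drop_candidates else
        sample(drop_candidates, 1L)
      keep <- setdiff(seq_len(n_ex), drop)
      models[[length(models) + 1L]] <- data.frame(
        gene = gene[i], model = paste0(gene[i], ".2"),
        start = starts[keep], end = ends[keep], strand = "+",
        stringsAsFactors = FALSE)
      classes[drop] <- "alternative"
    }
    exon_map[[length(exon_map) + 1L]] <- data.frame(
      gene = gene[i], exon = seq_len(n_ex), length_nt = ex_len,
      exon_class = classes, stringsAsFactors = FALSE)
    genes_bed[[length(genes_bed) + 1L]] <- data.frame(
      chrom = "chr1", start = starts[1L], end = ends[n_ex], gene = gene[i],
      stringsAsFactors = FALSE)
    cursor <- ends[n_ex] + sample(500:2000, 1L)
  }
  genes_bed <- do.call(rbind, genes_bed)

  # hotspots: anchored on RCP genes with boosted odds, otherwise anywhere
  chrom_len <- max(genes_bed$end) + 5000L
  w_gene <- ifelse(is_rcp, config$rcp_hotspot_boost, 1)
  hs <- lapply(seq_len(config$n_hotspots), function(k) {
    width <- sample(500:3000, 1L)
    if (stats::runif(1) < 0.3) {
      gi2 <- sample.int(n, 1L, prob = w_gene)
      centre <- round((genes_bed$start[gi2] + genes_bed$end[gi2]) / 2)
    } else centre <- sample.int(chrom_len, 1L)
    data.frame(chrom = "chr1", start = max(0L, centre - width %/% 2L),
               end = min(chrom_len, centre + width %/% 2L),
               stringsAsFactors = FALSE)
  })
  list(expression = list(raw = raw, present = present, probe_map = probe_map),
       half_lives = half_lives,
       gene_models = list(models = do.call(rbind, models),
                          exon_map = do.call(rbind, exon_map)),
       genes_bed = genes_bed,
       hotspots_bed = do.call(rbind, hs),
       rcp_flags = data.frame(gene = gene, is_rcp = is_rcp,
                              stringsAsFactors = FALSE))
}
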