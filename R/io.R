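# File interfaces. TSV is the universal tabular dialect ('#'-prefixed
# comment headers, tab separators); BED is 0-based half-open; FASTA ids
# must match across protein and CDS files. Every written table carries a
# header comment with the package version and, when given, the seed.

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file (wrapped lines are reassembled).
#' @param type `"AA"` or `"DNA"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path) else
    Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read an aligned FASTA file, checking row widths
#'
#' @param path Aligned FASTA.
#' @return Named character vector of equal-width rows.
#' @export
read_alignment <- function(path) {
  rows <- read_fasta(path, "AA")
  w <- nchar(rows)
  if (length(unique(w)) > 1L)
    stop("alignment rows of unequal length in ", path, ": ",
         names(rows)[which(w != w[1])[1]])
  rows
}

#' Write a data frame as commented TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @param comments Extra header comment lines.
#' @export
write_tsv <- function(df, path, seed = NULL, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("aarscan"))
  hdr <- c(paste0("# aarscan ", ver),
           if (!is.null(seed)) paste0("# seed: ", seed),
           "# coordinates in *_1based columns are 1-based inclusive; others 0-based half-open",
           if (length(comments) > 0L) paste0("# ", comments))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a commented TSV written by [write_tsv()] (or any plain TSV)
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a BED file (0-based half-open intervals)
#'
#' @param path BED3(+1) file.
#' @return Data frame with `chrom`, `start`, `end` and, if present, `name`.
#' @export
read_bed <- function(path) {
  d <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  names(d)[1:3] <- c("chrom", "start", "end")
  if (ncol(d) >= 4L) names(d)[4] <- "name"
  if (any(d$end < d$start)) stop("BED interval with end < start in ", path)
  d
}

#' Write a synthetic bundle to a directory of standard-format files
#'
#' Emits per-species protein and CDS FASTA, aligned FASTA per ortholog
#' group with a group manifest, disorder TSVs, expression/probe-map/
#' half-life TSVs, a gene-model exon table, gene and hotspot BED files,
#' and the ground-truth tract table.
#'
#' @param bundle An `aar_bundle` from [generate_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- bundle$config$seed
  pr <- bundle$proteins
  for (sp in unique(pr$species)) {
    d <- pr[pr$species == sp, ]
    write_fasta(stats::setNames(d$sequence, d$id),
                file.path(dir, paste0(sp, ".faa")))
    write_fasta(stats::setNames(d$cds, d$id),
                file.path(dir, paste0(sp, ".fna")))
  }
  write_tsv(bundle$truth_tracts, file.path(dir, "truth_tracts.tsv"), seed)
  if (!is.null(bundle$groups)) {
    msa_dir <- file.path(dir, "msa")
    dir.create(msa_dir, showWarnings = FALSE)
    manifest <- list()
    for (g in bundle$groups) {
      write_fasta(g$msa, file.path(msa_dir, paste0(g$group_id, ".afa")))
      manifest[[g$group_id]] <- data.frame(group_id = g$group_id,
                                           id = g$members$id,
                                           species = g$members$species,
                                           stringsAsFactors = FALSE)
    }
    write_tsv(do.call(rbind, manifest), file.path(dir, "groups.tsv"), seed)
  }
  if (!is.null(bundle$disorder))
    for (tr in names(bundle$disorder))
      write_tsv(bundle$disorder[[tr]],
                file.path(dir, paste0("disorder_", tr, ".tsv")), seed)
  if (!is.null(bundle$expression)) {
    expr <- data.frame(probe = rownames(bundle$expression$raw),
                       ifelse(bundle$expression$present,
                              round(bundle$expression$raw, 4), NA),
                       check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(expr, file.path(dir, "expression.tsv"), seed)
    write_tsv(bundle$expression$probe_map, file.path(dir, "probe_map.tsv"), seed)
    write_tsv(bundle$half_lives, file.path(dir, "half_lives.tsv"), seed)
    write_tsv(bundle$gene_models$models, file.path(dir, "gene_models.tsv"), seed)
    write_tsv(bundle$gene_models$exon_map, file.path(dir, "exon_map.tsv"), seed)
    utils::write.table(bundle$genes_bed, file.path(dir, "genes.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(bundle$hotspots_bed, file.path(dir, "hotspots.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(dir)
}
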