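# Plain-text readers and writers: FASTA via Biostrings, tab-separated
# reports with header lines. Display coordinate columns are 1-based
# closed; raw 0-based columns carry the `_0b` suffix.

#' Write loci to FASTA
#' @param loci a `locus` or list of loci.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(loci, path) {
  if (inherits(loci, "locus")) loci <- list(loci)
  x <- Biostrings::DNAStringSet(vapply(loci, `[[`, character(1), "sequence"))
  names(x) <- vapply(loci, `[[`, character(1), "id")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read loci from FASTA
#' @param path FASTA file.
#' @return list of [locus()] objects.
#' @export
read_loci_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  Map(locus, ids, as.character(x))
}

#' Write a small-RNA library to FASTA with count-annotated headers
#'
#' Headers follow the collapsed-read convention `>readNNNNNN_xCOUNT`.
#'
#' @param library an [srna_library()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_library_fasta <- function(library, path) {
  x <- Biostrings::DNAStringSet(library$sequence)
  names(x) <- sprintf("read%06d_x%d", seq_len(nrow(library)),
                      as.integer(library$count))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a small-RNA library from FASTA
#'
#' Counts are parsed from a `_xN` header suffix when present, else 1.
#'
#' @param path FASTA file.
#' @param name library name.
#' @param total_mapped optional CPM denominator override.
#' @return an [srna_library()].
#' @export
read_library_fasta <- function(path, name = basename(path),
                               total_mapped = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  cnt <- suppressWarnings(as.integer(sub("^.*_x(\\d+)\\s*$", "\\1", names(x))))
  cnt[is.na(cnt)] <- 1L
  srna_library(as.character(x), cnt, name = name, total_mapped = total_mapped)
}

#' Write a small-RNA library as two-column TSV (sequence, count)
#' @inheritParams write_library_fasta
#' @export
write_library_tsv <- function(library, path) {
  write.table(library[, c("sequence", "count")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a small-RNA library from two-column TSV (sequence, count)
#' @inheritParams read_library_fasta
#' @export
read_library_tsv <- function(path, name = basename(path),
                             total_mapped = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  srna_library(d$sequence, d$count, name = name, total_mapped = total_mapped)
}

#' Write alignments as TSV
#'
#' Columns: `read_seq`, `count`, `locus`, `start` / `end` (1-based closed),
#' `start_0b`, `strand`, and `cpm` when present.
#'
#' @param alignments data.frame from [map_reads()].
#' @param path output file.
#' @export
write_alignments_tsv <- function(alignments, path) {
  out <- data.frame(read_seq = alignments$sequence, count = alignments$count,
                    locus = alignments$locus_id,
                    start = alignments$start_0b + 1L, end = alignments$end_0b,
                    start_0b = alignments$start_0b, strand = alignments$strand,
                    stringsAsFactors = FALSE)
  if ("cpm" %in% names(alignments)) out$cpm <- alignments$cpm
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read alignments written by [write_alignments_tsv()]
#' @param path TSV file.
#' @return alignment data.frame in the internal layout.
#' @export
read_alignments_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  out <- data.frame(sequence = d$read_seq, count = d$count,
                    locus_id = d$locus, start_0b = d$start_0b,
                    end_0b = d$end, strand = d$strand,
                    length = d$end - d$start_0b, stringsAsFactors = FALSE)
  if ("cpm" %in% names(d)) out$cpm <- d$cpm
  out
}

#' Write a degradome profile as TSV (locus, position, position_0b, count)
#' @param profile a [degradome_profile()].
#' @param path output file.
#' @param drop_zero omit zero-count positions (default TRUE).
#' @export
write_degradome_tsv <- function(profile, path, drop_zero = TRUE) {
  pos <- seq_along(profile$counts) - 1L
  d <- data.frame(locus_id = profile$locus_id, position = pos + 1L,
                  position_0b = pos, count = profile$counts)
  if (drop_zero) d <- d[d$count > 0, , drop = FALSE]
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a degradome TSV into a profile
#' @param path TSV with columns `locus_id`, `position_0b`, `count`.
#' @param locus_length full locus length (positions absent from the file
#'   are zero).
#' @param total_mapped optional RPKM denominator override.
#' @return a [degradome_profile()].
#' @export
read_degradome_tsv <- function(path, locus_length, total_mapped = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  counts <- numeric(locus_length)
  counts[d$position_0b + 1L] <- d$count
  degradome_profile(unique(d$locus_id)[1], counts,
                    total_mapped = if (is.null(total_mapped)) sum(counts)
                                   else total_mapped)
}

#' Write RACE clones as TSV (locus, position, position_0b)
#' @param clones data.frame with `locus_id`, `position_0b`.
#' @param path output file.
#' @export
write_race_tsv <- function(clones, path) {
  d <- data.frame(locus_id = clones$locus_id,
                  position = clones$position_0b + 1L,
                  position_0b = clones$position_0b)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read RACE clones from TSV
#' @param path TSV with `locus_id`, `position_0b`.
#' @return data.frame with `locus_id`, `position_0b`.
#' @export
read_race_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  data.frame(locus_id = d$locus_id, position_0b = d$position_0b,
             stringsAsFactors = FALSE)
}

#' Read a gene set from a one-column TSV
#' @param path TSV whose first column holds gene identifiers.
#' @param label set label (default the file name).
#' @return a [gene_set()].
#' @export
read_gene_set_tsv <- function(path, label = basename(path)) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  gene_set(label, d[[1]])
}

#' Write a gene set as a one-column TSV
#' @param set a [gene_set()].
#' @param path output file.
#' @export
write_gene_set_tsv <- function(set, path) {
  write.table(data.frame(gene_id = set$members), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulation config as a flat key=value file
#' @param config a [sim_config()].
#' @param path output file.
#' @export
write_sim_config <- function(config, path) {
  fmt <- function(v) {
    if (is.character(v) && !is.null(names(v)) && length(v) > 1)
      paste(sprintf("%s:%s", names(v), v), collapse = ",")
    else paste(v, collapse = ",")
  }
  lines <- vapply(names(config),
                  function(k) sprintf("%s=%s", k, fmt(config[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a simulation config written by [write_sim_config()]
#' @param path key=value file.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  num <- function(k) as.numeric(strsplit(vals[[k]], ",")[[1]])
  gseq <- strsplit(vals[["guide_sequences"]], ",")[[1]]
  if (all(grepl(":", gseq, fixed = TRUE))) {
    parts <- strsplit(gseq, ":", fixed = TRUE)
    gseq <- stats::setNames(vapply(parts, `[`, character(1), 2L),
                            vapply(parts, `[`, character(1), 1L))
  }
  sim_config(seed = num("seed"), locus_length = num("locus_length"),
             gc_fraction = num("gc_fraction"), guide_sequences = gseq,
             site_start = num("site_start"),
             inter_site_gap = num("inter_site_gap"),
             n_duplexes_per_frame = num("n_duplexes_per_frame"),
             duplex_mean_count = num("duplex_mean_count"),
             duplex_dispersion = num("duplex_dispersion"),
             noise_fraction = num("noise_fraction"),
             degradome_peak_count = num("degradome_peak_count"),
             degradome_background_rate = num("degradome_background_rate"),
             n_race_clones = num("n_race_clones"),
             race_site_probs = num("race_site_probs"))
}
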