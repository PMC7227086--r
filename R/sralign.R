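# Exact small-RNA read placement and abundance normalisation.
#
# Mapping is exact-match on both strands with every occurrence reported
# (the "-a -v 0" contract): a read occurring at m positions yields m
# alignment rows, each carrying the read's full collapsed count. Reads or
# locus windows containing N never match.

#' Construct a locus
#'
#' A locus is a reference sequence (a transcript or gene-sized genomic
#' region) that defines the coordinate frame for all downstream analysis.
#'
#' @param id single string identifier.
#' @param sequence DNA string over A/C/G/T (N tolerated on load; N-containing
#'   windows never match reads).
#' @return an object of class `locus`: a list with `id` and `sequence`.
#' @export
locus <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("locus sequence must be non-empty")
  if (!grepl("^[ACGTN]+$", sequence))
    stop("locus sequence must contain only A/C/G/T/N")
  structure(list(id = id, sequence = sequence), class = "locus")
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("<locus> %s (%d nt)\n", x$id, nchar(x$sequence)))
  invisible(x)
}

locus_length <- function(x) nchar(x$sequence)

#' Build a collapsed small-RNA library
#'
#' Identical sequences are collapsed to one record with summed counts.
#' `total_mapped` is the CPM denominator; by default the sum of collapsed
#' counts, but a caller-supplied whole-library mapped total (as used when
#' normalising against a full tissue library) takes precedence.
#'
#' @param sequences character vector of read sequences.
#' @param counts integer vector of multiplicities (recycled 1 if missing).
#' @param name library name.
#' @param total_mapped CPM denominator; default `sum(counts)`.
#' @return object of class `srna_library`: data.frame with columns
#'   `sequence`, `count` and attributes `name`, `total_mapped`.
#' @export
srna_library <- function(sequences, counts = NULL, name = "library",
                         total_mapped = NULL) {
  if (is.null(counts)) counts <- rep(1L, length(sequences))
  stopifnot(length(sequences) == length(counts))
  if (any(counts < 1)) stop("collapsed read counts must be >= 1")
  sequences <- toupper(sequences)
  agg <- if (length(sequences)) {
    tab <- rowsum(as.numeric(counts), group = sequences)
    data.frame(sequence = rownames(tab), count = as.numeric(tab[, 1L]),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(sequence = character(0), count = numeric(0))
  }
  if (is.null(total_mapped)) total_mapped <- sum(agg$count)
  structure(agg, class = c("srna_library", "data.frame"),
            name = name, total_mapped = total_mapped)
}

#' CPM denominator of a library
#' @param library an `srna_library`.
#' @return numeric scalar.
#' @export
total_mapped <- function(library) attr(library, "total_mapped")

# All exact occurrences (overlap-aware) of `pattern` in `subject`.
# Returns 0-based starts. Patterns with N never match (v0 semantics);
# N in the subject never matches because patterns are plain ACGT.
exact_starts <- function(pattern, subject) {
  if (grepl("N", pattern, fixed = TRUE)) return(integer(0))
  m <- gregexpr(paste0("(?=", pattern, ")"), subject, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

#' Map reads to loci by exact matching on both strands
#'
#' Every exact occurrence of each read is reported: forward occurrences on
#' the sense strand, occurrences of the reverse complement on the antisense
#' strand. No mismatches, no gaps. Reads shorter than `min_len` or
#' containing non-ACGT characters are skipped with a warning that reports
#' how many were dropped.
#'
#' @param library an [srna_library()].
#' @param loci a `locus` or list of loci.
#' @param min_len minimum read length retained (default 15).
#' @return data.frame of alignments: `sequence`, `count`, `locus_id`,
#'   `start_0b`, `end_0b` (half-open), `strand`, `length`.
#' @export
map_reads <- function(library, loci, min_len = 15L) {
  if (inherits(loci, "locus")) loci <- list(loci)
  ok <- nchar(library$sequence) >= min_len & is_dna(library$sequence)
  n_skip <- sum(!ok)
  if (n_skip > 0L)
    warning(sprintf("skipped %d read(s) shorter than %d nt or with non-ACGT characters",
                    n_skip, min_len))
  reads <- library[ok, , drop = FALSE]
  rcs <- revcomp(reads$sequence)
  out <- list()
  for (lc in loci) {
    subject <- lc$sequence
    for (i in seq_len(nrow(reads))) {
      sq <- reads$sequence[i]; ct <- reads$count[i]; L <- nchar(sq)
      fwd <- exact_starts(sq, subject)
      rev <- exact_starts(rcs[i], subject)
      if (length(fwd))
        out[[length(out) + 1L]] <- data.frame(
          sequence = sq, count = ct, locus_id = lc$id, start_0b = fwd,
          end_0b = fwd + L, strand = "+", length = L,
          stringsAsFactors = FALSE)
      if (length(rev))
        out[[length(out) + 1L]] <- data.frame(
          sequence = sq, count = ct, locus_id = lc$id, start_0b = rev,
          end_0b = rev + L, strand = "-", length = L,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sequence = character(0), count = numeric(0),
                      locus_id = character(0), start_0b = integer(0),
                      end_0b = integer(0), strand = character(0),
                      length = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$locus_id, res$start_0b, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Counts-per-million normalisation of alignments
#'
#' CPM(read) = count * 1e6 / total_mapped. Multi-mapped reads carry their
#' full count at every placement (no fractional splitting), matching
#' all-alignment reporting.
#'
#' @param alignments data.frame from [map_reads()].
#' @param library the source [srna_library()] (its `total_mapped` is the
#'   denominator) or a numeric total.
#' @return `alignments` with a `cpm` column added.
#' @export
cpm_normalize <- function(alignments, library) {
  total <- if (is.numeric(library)) library else total_mapped(library)
  if (is.null(total) || total <= 0)
    stop("total_mapped must be > 0 for CPM normalization")
  alignments$cpm <- alignments$count * 1e6 / total
  alignments
}

#' Per-position 5'-end density profile
#'
#' Position p holds the summed count (and CPM when available) of reads
#' whose strand-aware 5' end is p: leftmost coordinate for `+` reads,
#' rightmost for `-` reads. Sense and antisense are reported separately.
#'
#' @param alignments alignments on one locus (optionally with `cpm`).
#' @param locus the `locus` the alignments refer to.
#' @return data.frame with one row per position: `pos_0b`, `sense`,
#'   `antisense` (raw counts) and `sense_cpm`, `antisense_cpm` when the
#'   input carries CPM values.
#' @export
density_profile <- function(alignments, locus) {
  L <- locus_length(locus)
  alignments <- alignments[alignments$locus_id == locus$id, , drop = FALSE]
  five_prime <- ifelse(alignments$strand == "+",
                       alignments$start_0b, alignments$end_0b - 1L)
  acc <- function(w, sel) {
    v <- numeric(L)
    if (any(sel)) {
      t <- rowsum(w[sel], group = five_prime[sel])
      v[as.integer(rownames(t)) + 1L] <- t[, 1L]
    }
    v
  }
  plus <- alignments$strand == "+"
  out <- data.frame(pos_0b = seq_len(L) - 1L,
                    sense = acc(alignments$count, plus),
                    antisense = acc(alignments$count, !plus))
  if ("cpm" %in% names(alignments)) {
    out$sense_cpm <- acc(alignments$cpm, plus)
    out$antisense_cpm <- acc(alignments$cpm, !plus)
  }
  out
}
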