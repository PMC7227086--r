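# miRNA / phasiRNA target scanning with G:U wobble handling.
#
# A guide is aligned antiparallel to every transcript window of its own
# length: guide nt i (1-based from the guide 5' end) pairs transcript
# position start + L - i. Pairs are classed Watson-Crick, G:U wobble
# (guide T vs target G, or guide G vs target T, i.e. a T-G pair in DNA
# space), or mismatch. G:U is never counted as a mismatch. The predicted
# slice coordinate is the first nucleotide of the 3' cleavage fragment,
# start + L - 10: the scissile bond faces guide nt 10/11.

#' Construct a guide RNA record
#'
#' @param name guide name.
#' @param sequence 18-24 nt guide, RNA or DNA alphabet (stored as DNA).
#' @return object of class `guide_rna`.
#' @export
guide_rna <- function(name, sequence) {
  sequence <- normalize_seq(sequence)
  if (!is_dna(sequence)) stop("guide must be over A/C/G/T (or U)")
  if (nchar(sequence) < 18L || nchar(sequence) > 24L)
    stop("guide length must be 18-24 nt")
  structure(list(name = name, sequence = sequence,
                 length_class = nchar(sequence)), class = "guide_rna")
}

COMP <- c(A = "T", C = "G", G = "C", T = "A")

# Classify antiparallel pairs of `guide` against one same-length target
# window (transcript sense, 5'->3'). Returns per-guide-position classes
# ("wc", "gu", "mm"), index 1 = guide 5' end.
classify_pairs <- function(guide, window) {
  L <- nchar(guide)
  stopifnot(nchar(window) == L)
  g <- strsplit(guide, "")[[1]]
  t <- rev(strsplit(window, "")[[1]])  # t[i] pairs guide nt i
  cls <- rep("mm", L)
  cls[COMP[g] == t] <- "wc"
  cls[(g == "T" & t == "G") | (g == "G" & t == "T")] <- "gu"
  cls
}

#' Score one guide::target duplex
#'
#' Penalty score: mismatch 1.0, G:U wobble 0.5, both doubled within guide
#' positions `seed_region` (default 2-13, the cleavage-critical region
#' counted from the guide 5' end). Pseudo-energy: per-pair table G:C -3.0,
#' A:T -2.0, G:U -1.0, mismatch +0.5 (a transparent fixed-table stand-in
#' for duplex stability, not a nearest-neighbour thermodynamic model).
#'
#' @param guide guide sequence (5'->3').
#' @param target_window transcript window of equal length (sense, 5'->3').
#' @param seed_region inclusive guide-position range with doubled penalties.
#' @return list with `score`, `energy`, `mismatches`, `gu_pairs`.
#' @export
duplex_score <- function(guide, target_window, seed_region = c(2L, 13L)) {
  guide <- normalize_seq(guide); target_window <- normalize_seq(target_window)
  if (nchar(guide) != nchar(target_window))
    stop("guide and target window must have equal length")
  cls <- classify_pairs(guide, target_window)
  g <- strsplit(guide, "")[[1]]
  pos <- seq_along(cls)
  w <- ifelse(pos >= seed_region[1] & pos <= seed_region[2], 2, 1)
  pen <- ifelse(cls == "mm", 1, ifelse(cls == "gu", 0.5, 0))
  en <- ifelse(cls == "mm", 0.5,
        ifelse(cls == "gu", -1,
        ifelse(g %in% c("G", "C"), -3, -2)))
  list(score = sum(pen * w), energy = sum(en),
       mismatches = sum(cls == "mm"), gu_pairs = sum(cls == "gu"))
}

# Vectorised window classification of one guide against one transcript
# sequence: per-window mismatch and G:U tallies without materialising every
# window string.
scan_windows <- function(guide, tseq) {
  L <- nchar(guide); W <- nchar(tseq) - L + 1L
  if (W < 1L) return(data.frame(start_0b = integer(0), mismatches = integer(0),
                                gu = integer(0)))
  g <- strsplit(guide, "")[[1]]
  starts <- seq_len(W)  # 1-based window starts
  mm <- integer(W); gu <- integer(W)
  for (i in seq_len(L)) {
    # guide nt i pairs transcript offset L - i within the window
    tch <- substring(tseq, starts + L - i, starts + L - i)
    gi <- g[i]
    is_wc <- tch == COMP[[gi]]
    is_gu <- (gi == "T" & tch == "G") | (gi == "G" & tch == "T")
    mm <- mm + as.integer(!(is_wc | is_gu))
    gu <- gu + as.integer(is_gu)
  }
  data.frame(start_0b = starts - 1L, mismatches = mm, gu = gu)
}

scan_targets_core <- function(guides, transcripts, max_mismatch, max_gu) {
  if (inherits(transcripts, "locus")) transcripts <- list(transcripts)
  if (is.character(transcripts)) {
    ids <- names(transcripts)
    if (is.null(ids)) ids <- paste0("transcript", seq_along(transcripts))
    transcripts <- Map(locus, ids, transcripts)
  }
  out <- list()
  for (gn in names(guides)) {
    gseq <- guides[[gn]]; L <- nchar(gseq)
    for (tx in transcripts) {
      sc <- scan_windows(gseq, tx$sequence)
      hit <- sc[sc$mismatches <= max_mismatch & sc$gu <= max_gu, , drop = FALSE]
      if (!nrow(hit)) next
      ds <- lapply(hit$start_0b, function(s)
        duplex_score(gseq, substring(tx$sequence, s + 1L, s + L)))
      out[[length(out) + 1L]] <- data.frame(
        guide = gn, transcript_id = tx$id, start_0b = hit$start_0b,
        end_0b = hit$start_0b + L, length = L,
        mismatches = hit$mismatches, gu_pairs = hit$gu,
        score = vapply(ds, `[[`, numeric(1), "score"),
        energy = vapply(ds, `[[`, numeric(1), "energy"),
        slice_coord_0b = hit$start_0b + L - 10L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(guide = character(0), transcript_id = character(0),
                      start_0b = integer(0), end_0b = integer(0),
                      length = integer(0), mismatches = integer(0),
                      gu_pairs = integer(0), score = numeric(0),
                      energy = numeric(0), slice_coord_0b = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

as_named_guides <- function(guides) {
  if (inherits(guides, "guide_rna"))
    guides <- stats::setNames(guides$sequence, guides$name)
  guides <- vapply(guides, normalize_seq, character(1))
  if (is.null(names(guides)) || any(names(guides) == ""))
    names(guides) <- paste0("guide", seq_along(guides))
  guides
}

#' Scan transcripts for miRNA target sites
#'
#' Reverse-complementarity scan allowing up to `max_mismatch` mismatches
#' and `max_gu_bulge` G:U wobbles ("T-G" pairs in DNA space); G:U is not
#' counted as a mismatch. Each hit carries its duplex penalty score,
#' pseudo-energy, and predicted slice coordinate.
#'
#' @param guides a [guide_rna()], named character vector, or list.
#' @param transcripts [locus()] (or list thereof) or named character vector.
#' @param max_mismatch mismatch budget (default 3).
#' @param max_gu_bulge G:U budget (default 1).
#' @return data.frame of target sites (see [scan_phasirna_targets()] for
#'   the same columns): `guide`, `transcript_id`, `start_0b`, `end_0b`,
#'   `length`, `mismatches`, `gu_pairs`, `score`, `energy`,
#'   `slice_coord_0b`.
#' @export
scan_mirna_targets <- function(guides, transcripts, max_mismatch = 3L,
                               max_gu_bulge = 1L) {
  guides <- as_named_guides(guides)
  if (any(nchar(guides) < 18L)) stop("guides must be >= 18 nt")
  scan_targets_core(guides, transcripts, max_mismatch, max_gu_bulge)
}

#' Scan transcripts for phasiRNA target sites
#'
#' As [scan_mirna_targets()] but with the stricter phasiRNA mismatch budget
#' (default 2). G:U wobbles are allowed by default without limit; they are
#' never counted as mismatches and enter the penalty score at half weight.
#'
#' @param candidates phasiRNA candidates: a data.frame with `name` and
#'   `sequence` columns (as from [call_phasirnas()]) or a named character
#'   vector of 20-22 nt sequences.
#' @param transcripts [locus()] (or list thereof) or named character vector.
#' @param max_mismatch mismatch budget (default 2).
#' @param max_gu G:U budget (default `Inf`).
#' @return data.frame of target sites; columns as [scan_mirna_targets()].
#' @export
scan_phasirna_targets <- function(candidates, transcripts, max_mismatch = 2L,
                                  max_gu = Inf) {
  if (is.data.frame(candidates))
    candidates <- stats::setNames(candidates$sequence, candidates$name)
  candidates <- as_named_guides(candidates)
  if (any(nchar(candidates) < 20L | nchar(candidates) > 22L))
    stop("phasiRNA candidate sequences must be 20-22 nt")
  scan_targets_core(candidates, transcripts, max_mismatch, max_gu)
}

#' Predicted slice coordinate of a target site
#'
#' The cut lies between the target bases pairing guide nt 10 and 11, so
#' the first nucleotide of the 3' cleavage fragment is `start + L - 10`.
#' This coordinate is also the expected degradome 5'-end peak and, for
#' trigger sites, the phasing-frame anchor.
#'
#' @param site a target-site data.frame (rows from the scanners) or a list
#'   with `start_0b` and `length` (or `end_0b`).
#' @return integer vector of 0-based slice coordinates.
#' @export
predicted_slice_coord <- function(site) {
  len <- if (!is.null(site$length)) site$length else site$end_0b - site$start_0b
  as.integer(site$start_0b + len - 10L)
}
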