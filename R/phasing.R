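# Phasing-score computation and two-frame register detection.
#
# A phasing frame is the 21-nt register anchored at the first nucleotide of
# a trigger miRNA's 3' cleavage fragment. The phasing score over an
# eight-cycle sliding window is P = (n - 2) * ln(1 + k), where n is the
# number of the 8 cycle positions occupied by at least one read and k the
# total in-phase read count in the window; P = 0 when n <= 2, and a frame
# is called when the maximum window P exceeds the cutoff (default 5).
# Antisense reads join the register through the 2-nt 3'-overhang rule:
# leftmost coordinate + 2 must be congruent to the anchor modulo 21.

#' Construct a phasing frame
#'
#' @param locus_id locus identifier.
#' @param anchor 0-based coordinate of the first nucleotide of the trigger's
#'   3' cleavage fragment.
#' @param label frame label, e.g. `"PF1"`.
#' @param trigger optional trigger guide name.
#' @return object of class `phasing_frame`.
#' @export
phasing_frame <- function(locus_id, anchor, label = "PF1", trigger = NA_character_) {
  stopifnot(length(anchor) == 1L, anchor >= 0)
  structure(list(locus_id = locus_id, anchor = as.integer(anchor),
                 interval = 21L, label = label, trigger = trigger),
            class = "phasing_frame")
}

#' @export
print.phasing_frame <- function(x, ...) {
  cat(sprintf("<phasing_frame> %s on %s, anchor %d (register %d mod 21)\n",
              x$label, x$locus_id, x$anchor, x$anchor %% 21L))
  invisible(x)
}

# Strand-resolved in-phase counts: matrix with rows "+" and "-", one column
# per duplex cycle 1..n_cycles.
inphase_counts_matrix <- function(alignments, frame, length_range = c(20L, 22L),
                                  n_cycles = NULL, strands = c("+", "-")) {
  a <- alignments[alignments$locus_id == frame$locus_id &
                    alignments$length >= length_range[1] &
                    alignments$length <= length_range[2] &
                    alignments$strand %in% strands, , drop = FALSE]
  anchor <- frame$anchor
  eff <- ifelse(a$strand == "+", a$start_0b, a$start_0b + 2L)
  keep <- eff >= anchor & (eff - anchor) %% 21L == 0L
  a <- a[keep, , drop = FALSE]
  cyc <- (ifelse(a$strand == "+", a$start_0b, a$start_0b + 2L) - anchor) %/% 21L + 1L
  if (is.null(n_cycles)) n_cycles <- if (length(cyc)) max(cyc) else 0L
  m <- matrix(0, nrow = 2L, ncol = n_cycles,
              dimnames = list(c("+", "-"), NULL))
  keep2 <- cyc <= n_cycles
  a <- a[keep2, , drop = FALSE]; cyc <- cyc[keep2]
  for (s in c("+", "-")) {
    sel <- a$strand == s
    if (any(sel)) {
      t <- rowsum(a$count[sel], group = cyc[sel])
      m[s, as.integer(rownames(t))] <- t[, 1L]
    }
  }
  m
}

#' In-phase read counts per duplex cycle
#'
#' A `+` read with 5' start s belongs to cycle `(s - anchor)/21 + 1` when
#' `s >= anchor` and `s` is congruent to the anchor modulo 21; a `-` read
#' belongs to the register when its leftmost coordinate + 2 is congruent to
#' the anchor (the 2-nt 3'-overhang rule). Reads outside `length_range`
#' are ignored.
#'
#' @param alignments alignment data.frame from [map_reads()].
#' @param frame a [phasing_frame()].
#' @param length_range inclusive read-length window (default 20-22 nt; the
#'   loci also emit 18-29 nt products, configurable accordingly).
#' @param n_cycles total number of cycles to report (zero-padded); default
#'   the last occupied cycle.
#' @param strands strands counted toward the register (default both).
#' @return numeric vector of per-cycle summed counts (cycle 1 = the anchor).
#' @export
inphase_counts <- function(alignments, frame, length_range = c(20L, 22L),
                           n_cycles = NULL, strands = c("+", "-")) {
  colSums(inphase_counts_matrix(alignments, frame, length_range, n_cycles,
                                strands))
}

#' Windowed phasing-score profile
#'
#' Slides an `window`-cycle window by one cycle over the per-cycle counts;
#' each window scores P = (n - 2) * ln(1 + k_total) when n > 2, else 0.
#' Windows with fewer than `window` cycles remaining are not scored. The
#' profile's summary score is the maximum window P.
#'
#' @param cycle_counts numeric vector from [inphase_counts()].
#' @param cutoff calling threshold attached to the profile (default 5).
#' @param window cycles per window (default 8).
#' @return object of class `phasing_profile`: data.frame with columns
#'   `window_start_cycle`, `n`, `k_total`, `P`; attributes `cutoff` and
#'   `score` (max P, 0 when no window fits).
#' @export
phasing_score_profile <- function(cycle_counts, cutoff = 5, window = 8L) {
  if (any(cycle_counts < 0)) stop("cycle counts must be non-negative")
  m <- length(cycle_counts)
  n_win <- max(0L, m - window + 1L)
  if (n_win > 0L) {
    occ <- as.numeric(cycle_counts > 0)
    csum_k <- c(0, cumsum(cycle_counts))
    csum_n <- c(0, cumsum(occ))
    i <- seq_len(n_win)
    k_total <- csum_k[i + window] - csum_k[i]
    n <- csum_n[i + window] - csum_n[i]
    P <- ifelse(n > 2, (n - 2) * log1p(k_total), 0)
    df <- data.frame(window_start_cycle = i, n = as.integer(n),
                     k_total = k_total, P = P)
  } else {
    df <- data.frame(window_start_cycle = integer(0), n = integer(0),
                     k_total = numeric(0), P = numeric(0))
  }
  structure(df, class = c("phasing_profile", "data.frame"),
            cutoff = cutoff, score = if (nrow(df)) max(df$P) else 0)
}

#' Summary phasing score of a profile
#' @param profile a `phasing_profile`.
#' @return maximum window P.
#' @export
phasing_score <- function(profile) attr(profile, "score")

#' Detect phasing frames on a locus
#'
#' With `anchors` supplied (annotated cleavage coordinates, e.g. predicted
#' slice sites), scores each anchor's frame. Without anchors, scans all 21
#' registers de novo (anchor residues 0..20) and reports every register
#' whose maximum window P exceeds the cutoff. Two surviving registers on
#' one locus constitute a two-frame call. Ranking: higher P, then higher
#' window k_total, then smaller residue; de novo labels PF1, PF2, ... are
#' assigned in rank order, anchored labels in input order.
#'
#' @param alignments alignment data.frame from [map_reads()].
#' @param locus the [locus()] scanned.
#' @param anchors optional numeric vector of 0-based anchor coordinates, or
#'   a data.frame with columns `coordinate` and optionally `trigger`.
#' @param cutoff phasing-score threshold (default 5).
#' @param length_range read lengths counted (default 20-22).
#' @param window cycles per scoring window (default 8).
#' @param strands strands counted toward n and k (default both).
#' @return data.frame with one row per scored frame: `locus_id`, `label`,
#'   `anchor`, `residue`, `score`, `best_n`, `best_k`, `pass`; attribute
#'   `profiles` holds the named list of `phasing_profile`s. De novo calls
#'   only include passing registers.
#' @export
detect_frames <- function(alignments, locus, anchors = NULL, cutoff = 5,
                          length_range = c(20L, 22L), window = 8L,
                          strands = c("+", "-")) {
  L <- locus_length(locus)
  if (L < window * 21L)
    stop(sprintf("locus too short for an %d-cycle window (%d nt needed)",
                 window, window * 21L))
  trigger <- NULL
  if (is.data.frame(anchors)) {
    trigger <- if ("trigger" %in% names(anchors)) anchors$trigger else NULL
    anchors <- anchors$coordinate
  }
  de_novo <- is.null(anchors)
  if (de_novo) anchors <- 0:20
  rows <- list(); profiles <- list()
  for (i in seq_along(anchors)) {
    fr <- phasing_frame(locus$id, anchors[i], label = sprintf("F%d", i),
                        trigger = if (!is.null(trigger)) trigger[i] else NA)
    n_cyc <- (L - fr$anchor) %/% 21L
    cc <- inphase_counts(alignments, fr, length_range, n_cycles = n_cyc,
                         strands = strands)
    prof <- phasing_score_profile(cc, cutoff = cutoff, window = window)
    sc <- phasing_score(prof)
    best <- if (nrow(prof) && sc > 0) which.max(prof$P) else NA_integer_
    rows[[i]] <- data.frame(
      locus_id = locus$id, label = NA_character_, anchor = fr$anchor,
      residue = fr$anchor %% 21L, score = sc,
      best_n = if (is.na(best)) 0L else prof$n[best],
      best_k = if (is.na(best)) 0 else prof$k_total[best],
      pass = sc > cutoff, stringsAsFactors = FALSE)
    profiles[[i]] <- prof
  }
  res <- do.call(rbind, rows)
  if (de_novo) {
    keep <- which(res$pass)
    ord <- keep[order(-res$score[keep], -res$best_k[keep], res$residue[keep])]
    res <- res[ord, , drop = FALSE]
    profiles <- profiles[ord]
    res$label <- if (nrow(res)) sprintf("PF%d", seq_len(nrow(res))) else character(0)
  } else {
    res$label <- sprintf("PF%d", seq_len(nrow(res)))
  }
  rownames(res) <- NULL
  names(profiles) <- res$label
  structure(res, profiles = profiles)
}

#' Call and name phasiRNA candidates in a frame
#'
#' Emits one candidate per (cycle, strand) whose in-phase summed count
#' reaches `min_count`, named `PFx_3'Dn(+/-)`. Sense candidates start at
#' `anchor + 21*(d-1)`; antisense candidates start 2 nt left of that (2-nt
#' 3'-overhang geometry).
#'
#' @param frame a [phasing_frame()].
#' @param alignments alignment data.frame.
#' @param min_count minimum summed in-phase count (>= 1).
#' @param length_range read lengths counted (default 20-22).
#' @param locus optional [locus()]; when given, candidate sequences are
#'   extracted from it.
#' @param library_total optional CPM denominator; adds a `cpm` column.
#' @return data.frame of candidates: `name`, `label`, `duplex_index`,
#'   `strand`, `start_0b`, `end_0b`, `length`, `count` (and `cpm`,
#'   `sequence` when computable).
#' @export
call_phasirnas <- function(frame, alignments, min_count = 1,
                           length_range = c(20L, 22L), locus = NULL,
                           library_total = NULL) {
  if (min_count < 1) stop("min_count must be >= 1")
  n_cyc <- NULL
  if (!is.null(locus)) n_cyc <- (locus_length(locus) - frame$anchor) %/% 21L
  m <- inphase_counts_matrix(alignments, frame, length_range, n_cycles = n_cyc)
  hits <- which(m >= min_count, arr.ind = TRUE)
  if (!nrow(hits))
    return(data.frame(name = character(0), label = character(0),
                      duplex_index = integer(0), strand = character(0),
                      start_0b = integer(0), end_0b = integer(0),
                      length = integer(0), count = numeric(0)))
  strand <- rownames(m)[hits[, "row"]]
  d <- hits[, "col"]
  sense_start <- frame$anchor + 21L * (d - 1L)
  start <- ifelse(strand == "+", sense_start, sense_start - 2L)
  out <- data.frame(
    name = sprintf("%s_3'D%d(%s)", frame$label, d, strand),
    label = frame$label, duplex_index = as.integer(d), strand = strand,
    start_0b = as.integer(start), end_0b = as.integer(start + 21L),
    length = 21L, count = m[hits], stringsAsFactors = FALSE)
  out <- out[order(out$duplex_index, out$strand), , drop = FALSE]
  if (!is.null(library_total)) out$cpm <- out$count * 1e6 / library_total
  if (!is.null(locus)) {
    sq <- substring(locus$sequence, out$start_0b + 1L, out$end_0b)
    out$sequence <- ifelse(out$strand == "+", sq, revcomp(sq))
  }
  rownames(out) <- NULL
  out
}

#' Register offset between two frames
#'
#' @param frameA,frameB [phasing_frame()]s on the same locus.
#' @return `(anchorB - anchorA) mod 21`, in `[0, 20]`. Zero means the two
#'   anchors share a register even if they are distinct frames.
#' @export
frame_offset <- function(frameA, frameB) {
  if (!identical(frameA$locus_id, frameB$locus_id))
    stop("frames are on different loci")
  (frameB$anchor - frameA$anchor) %% 21L
}
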