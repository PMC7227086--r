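# Synthetic two-frame phasiRNA locus generator with recorded ground truth.
#
# The generator emulates the study system: a transcript carrying two miRNA
# target sites separated by a short gap (12 nt by default, too short for a
# 21-nt product between the sites), each cleavage site anchoring its own
# 21-nt phasing frame on an independent transcript copy. Phased 21-nt
# duplexes are emitted downstream of each anchor with the canonical DCL
# 2-nt 3'-overhang geometry, with negative-binomial per-strand abundances,
# plus uniform positional noise of 18-29 nt. Degradome 5'-end profiles,
# multinomial RACE clones and gene sets with controlled overlap complete
# the ground-truthed inputs for every downstream stage.

#' Simulation configuration
#'
#' Bundles and validates all generator parameters. Defaults reproduce the
#' studied two-frame geometry: a 22-nt and a 21-nt trigger guide whose
#' target sites are separated by a 12-nt gap, placing the two cleavage
#' anchors 33 nt apart (frame offset 33 mod 21 = 12).
#'
#' @param seed integer RNG seed; every generator is deterministic given it.
#' @param locus_length locus length in nt (default 1500).
#' @param gc_fraction expected GC proportion in `[0,1]`.
#' @param guide_sequences named character vector of trigger guides, each 21
#'   or 22 nt (RNA accepted, stored as DNA). Default: one random 22-nt and
#'   one random 21-nt guide drawn from `seed`.
#' @param site_start 0-based start of the first implanted target site.
#' @param inter_site_gap nt between the 3' end of the first site and the 5'
#'   end of the second (default 12).
#' @param n_duplexes_per_frame phased duplex positions per frame (default 10).
#' @param duplex_mean_count expected reads per duplex strand (default 10).
#' @param duplex_dispersion negative-binomial size parameter; `Inf` gives
#'   Poisson counts (default 5, overdispersed as typical of sRNA data).
#' @param noise_fraction expected proportion of reads placed uniformly at
#'   random with length 18-29 nt (default 0.2).
#' @param degradome_peak_count expected degradome reads at each true slice
#'   site (default 50).
#' @param degradome_background_rate expected background degradome reads per
#'   position (default 1).
#' @param n_race_clones number of RACE clones (default 35).
#' @param race_site_probs probability vector over candidate slice sites;
#'   default `(2, 9, 23, 1)/35`, the four-site cis-cleavage scenario.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       locus_length = 1500L,
                       gc_fraction = 0.5,
                       guide_sequences = NULL,
                       site_start = 100L,
                       inter_site_gap = 12L,
                       n_duplexes_per_frame = 10L,
                       duplex_mean_count = 10,
                       duplex_dispersion = 5,
                       noise_fraction = 0.2,
                       degradome_peak_count = 50,
                       degradome_background_rate = 1,
                       n_race_clones = 35L,
                       race_site_probs = c(2, 9, 23, 1) / 35) {
  if (is.null(guide_sequences)) {
    guide_sequences <- with_seed(seed + 104729L, c(
      trigger22 = paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = ""),
      trigger21 = paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")))
  }
  guide_sequences <- vapply(guide_sequences, normalize_seq, character(1))
  if (length(guide_sequences) == 0L) stop("at least one guide is required")
  if (!all(nchar(guide_sequences) %in% c(21L, 22L)))
    stop("guide lengths must be 21 or 22 nt")
  if (!all(is_dna(guide_sequences)))
    stop("guides must be A/C/G/T (or RNA with U)")
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must be in [0,1]")
  if (noise_fraction < 0 || noise_fraction > 1)
    stop("noise_fraction must be in [0,1]")
  if (inter_site_gap < 0) stop("inter_site_gap must be >= 0")
  for (nm in c("locus_length", "site_start", "n_duplexes_per_frame",
               "duplex_mean_count", "degradome_peak_count",
               "degradome_background_rate", "n_race_clones"))
    stop_if_not_scalar_count(get(nm), nm)
  if (duplex_dispersion <= 0) stop("duplex_dispersion must be > 0 (Inf = Poisson)")
  if (abs(sum(race_site_probs) - 1) > 1e-9)
    stop("race_site_probs must sum to 1 (tolerance 1e-9)")
  if (any(race_site_probs < 0)) stop("race_site_probs must be non-negative")
  structure(list(
    seed = as.integer(seed), locus_length = as.integer(locus_length),
    gc_fraction = gc_fraction, guide_sequences = guide_sequences,
    site_start = as.integer(site_start),
    inter_site_gap = as.integer(inter_site_gap),
    n_duplexes_per_frame = as.integer(n_duplexes_per_frame),
    duplex_mean_count = duplex_mean_count,
    duplex_dispersion = duplex_dispersion,
    noise_fraction = noise_fraction,
    degradome_peak_count = degradome_peak_count,
    degradome_background_rate = degradome_background_rate,
    n_race_clones = as.integer(n_race_clones),
    race_site_probs = race_site_probs), class = "sim_config")
}

site_span <- function(config) {
  sum(nchar(config$guide_sequences)) +
    config$inter_site_gap * (length(config$guide_sequences) - 1L)
}

#' Generate a random locus sequence
#'
#' Draws a random sequence of the configured length and expected GC
#' fraction. No target sites are present yet; see [implant_target_sites()].
#'
#' @param config a [sim_config()].
#' @return a [locus()] named `"synthetic_locus"`.
#' @export
generate_locus <- function(config) {
  need <- config$site_start + site_span(config)
  if (config$locus_length < need)
    stop(sprintf("degenerate geometry: locus_length %d cannot hold sites ending at %d",
                 config$locus_length, need))
  gc <- config$gc_fraction
  seq <- with_seed(config$seed, paste(
    sample(c("A", "C", "G", "T"), config$locus_length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""))
  locus("synthetic_locus", seq)
}

#' Implant miRNA target sites into a locus
#'
#' Writes the exact reverse complement of each guide into the locus,
#' consecutive sites separated by `gap` nt, and records each site interval
#' plus its predicted slice coordinate (cleavage between guide nt 10 and
#' 11, so the first nucleotide of the 3' cleavage fragment sits at
#' `start + L - 10`). The slice coordinates double as phasing-frame anchors.
#'
#' @param locus a [locus()].
#' @param guides named character vector of guide sequences (5'->3').
#' @param gap nt between consecutive site intervals.
#' @param start 0-based start coordinate of the first site.
#' @return list with elements `locus` (sites implanted) and `truth`, a
#'   `truth_record` holding `site_coords` (guide, start_0b, end_0b,
#'   slice_coord_0b), `frame_anchors`, and both inter-site distance
#'   conventions (`gap_between_sites`, `anchor_separations`).
#' @export
implant_target_sites <- function(locus, guides, gap = 12L, start = 100L) {
  if (length(guides) == 0L) stop("guides must be non-empty")
  if (gap < 0) stop("gap must be >= 0")
  guides <- vapply(guides, normalize_seq, character(1))
  if (is.null(names(guides)) || any(names(guides) == ""))
    names(guides) <- paste0("guide", seq_along(guides))
  lens <- unname(nchar(guides))
  starts <- start + cumsum(c(0L, (lens + gap)[-length(lens)]))
  ends <- starts + lens
  if (max(ends) > locus_length(locus))
    stop("geometry error: target sites extend past the locus end")
  seq <- locus$sequence
  for (i in seq_along(guides)) {
    substr(seq, starts[i] + 1L, ends[i]) <- revcomp(guides[[i]])
  }
  slice <- starts + lens - 10L
  truth <- structure(list(
    locus_id = locus$id,
    site_coords = data.frame(guide = names(guides), start_0b = starts,
                             end_0b = ends, slice_coord_0b = slice,
                             stringsAsFactors = FALSE, row.names = NULL),
    frame_anchors = slice,
    gap_between_sites = gap,
    anchor_separations = diff(slice)), class = "truth_record")
  list(locus = locus(locus$id, seq), truth = truth)
}

nb_draw <- function(n, mu, size) {
  if (is.infinite(size)) rpois(n, mu) else rnbinom(n, size = size, mu = mu)
}

#' Simulate phased small-RNA reads from the frame anchors
#'
#' For each frame anchor c and duplex index d, emits a sense 21-mer with 5'
#' end at `c + 21*(d-1)` and its antisense duplex partner with 2-nt
#' 3'-overhangs (antisense leftmost coordinate = sense 5' - 2). Per-strand
#' counts are negative binomial. Uniform noise reads (random position,
#' strand, and length 18-29 nt) are added so that the expected noise
#' proportion equals `noise_fraction`; noise reads are drawn to fit inside
#' the locus, preserving the length distribution.
#'
#' @param locus the implanted [locus()].
#' @param truth the `truth_record` from [implant_target_sites()].
#' @param config a [sim_config()].
#' @return list with `library` (an [srna_library()]) and `truth` extended
#'   with `duplex_reads` (frame, duplex, strand, start_0b, sequence, count),
#'   `noise_reads`, and `library_total`.
#' @export
simulate_phased_reads <- function(locus, truth, config) {
  anchors <- truth$frame_anchors
  if (length(anchors) < 1L) stop("truth must contain at least one frame anchor")
  L <- locus_length(locus)
  n_dup <- config$n_duplexes_per_frame
  if (any(anchors + 21L * n_dup > L))
    stop(sprintf("geometry error: %d duplex cycles exceed the locus length", n_dup))
  if (any(anchors < 2L))
    stop("geometry error: anchor too close to the locus start for the 2-nt overhang")
  with_seed(config$seed + 1L, {
    rows <- list()
    for (f in seq_along(anchors)) {
      p <- anchors[f] + 21L * (seq_len(n_dup) - 1L)
      cnt_s <- nb_draw(n_dup, config$duplex_mean_count, config$duplex_dispersion)
      cnt_a <- nb_draw(n_dup, config$duplex_mean_count, config$duplex_dispersion)
      if (config$noise_fraction == 1) { cnt_s[] <- 0; cnt_a[] <- 0 }
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, duplex = seq_len(n_dup), strand = "+", start_0b = p,
        sequence = substring(locus$sequence, p + 1L, p + 21L),
        count = cnt_s, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, duplex = seq_len(n_dup), strand = "-", start_0b = p - 2L,
        sequence = revcomp(substring(locus$sequence, p - 1L, p + 19L)),
        count = cnt_a, stringsAsFactors = FALSE)
    }
    phased <- do.call(rbind, rows)
    total_phased <- sum(phased$count)
    nf <- config$noise_fraction
    n_noise <- if (nf == 0) 0L
      else if (nf == 1) rpois(1L, 2 * length(anchors) * n_dup * config$duplex_mean_count)
      else rpois(1L, total_phased * nf / (1 - nf))
    noise <- if (n_noise > 0L) {
      len <- sample(18:29, n_noise, replace = TRUE)
      st <- as.integer(floor(runif(n_noise) * (L - len + 1L)))
      sq <- substring(locus$sequence, st + 1L, st + len)
      min <- sample(c("+", "-"), n_noise, replace = TRUE)
      sq[min == "-"] <- revcomp(sq[min == "-"])
      data.frame(id = paste0("noise_", seq_len(n_noise)), strand = min,
                 start_0b = st, length = len, sequence = sq, count = 1L,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id = character(0), strand = character(0),
                 start_0b = integer(0), length = integer(0),
                 sequence = character(0), count = integer(0))
    }
    keep <- phased$count > 0
    lib <- srna_library(c(phased$sequence[keep], noise$sequence),
                        c(phased$count[keep], noise$count),
                        name = sprintf("sim_seed%d", config$seed))
    truth$duplex_reads <- phased
    truth$noise_reads <- noise
    truth$noise_read_ids <- noise$id
    truth$library_total <- sum(phased$count) + sum(noise$count)
    list(library = lib, truth = truth)
  })
}

#' Simulate a degradome 5'-end profile
#'
#' Per-position counts are Poisson background everywhere, plus an extra
#' Poisson peak at each true slice coordinate (and at any additional
#' phasiRNA-guided slice coordinates supplied).
#'
#' @param locus the [locus()].
#' @param truth `truth_record` with at least one slice coordinate.
#' @param config a [sim_config()].
#' @param extra_sites optional additional 0-based slice coordinates to peak.
#' @return a [degradome_profile()].
#' @export
simulate_degradome <- function(locus, truth, config, extra_sites = NULL) {
  sites <- c(truth$site_coords$slice_coord_0b, extra_sites)
  if (length(sites) < 1L) stop("truth must contain at least one slice coordinate")
  L <- locus_length(locus)
  if (any(sites < 0L | sites >= L)) stop("slice coordinates outside the locus")
  with_seed(config$seed + 2L, {
    counts <- rpois(L, config$degradome_background_rate)
    counts[sites + 1L] <- counts[sites + 1L] +
      rpois(length(sites), config$degradome_peak_count)
    degradome_profile(locus$id, counts)
  })
}

#' Simulate RLM-RACE clone positions
#'
#' Clone 5'-end coordinates are drawn multinomially over the candidate
#' slice coordinates with probabilities `race_site_probs`.
#'
#' @param truth `truth_record` (provides default candidate sites).
#' @param config a [sim_config()].
#' @param sites candidate 0-based slice coordinates; default the truth's
#'   frame anchors. Must match `race_site_probs` in length.
#' @return data.frame of clones: `locus_id`, `position_0b`.
#' @export
simulate_race_clones <- function(truth, config, sites = truth$frame_anchors) {
  probs <- config$race_site_probs
  if (length(probs) != length(sites))
    stop("race_site_probs length must equal the number of candidate sites")
  if (abs(sum(probs) - 1) > 1e-9) stop("race_site_probs must sum to 1")
  with_seed(config$seed + 3L, {
    if (config$n_race_clones == 0L)
      return(data.frame(locus_id = character(0), position_0b = integer(0)))
    tally <- as.integer(rmultinom(1L, config$n_race_clones, probs))
    data.frame(locus_id = truth$locus_id,
               position_0b = rep(as.integer(sites), tally),
               stringsAsFactors = FALSE)
  })
}

#' Simulate up/down-regulated gene sets with controlled overlap
#'
#' Builds two labelled gene sets per direction whose sizes and pairwise
#' intersections are exactly as requested, for exercising the Venn/Fisher
#' reporting stage.
#'
#' @param n_up_A,n_up_B,n_up_shared sizes and intersection of the
#'   up-regulated sets.
#' @param n_down_A,n_down_B,n_down_shared same for the down-regulated sets.
#' @param seed RNG seed (identifier shuffling only).
#' @return list with `up` and `down`, each a list of two [gene_set()]s
#'   `A` and `B`.
#' @export
simulate_deg_tables <- function(n_up_A, n_up_B, n_up_shared,
                                n_down_A, n_down_B, n_down_shared,
                                seed = 1L) {
  make_pair <- function(nA, nB, nsh, prefix) {
    if (nsh > min(nA, nB))
      stop("shared size exceeds one of the set sizes")
    ids <- sprintf("%s_gene%05d", prefix, seq_len(nA + nB - nsh))
    shared <- ids[seq_len(nsh)]
    onlyA <- ids[nsh + seq_len(nA - nsh)]
    onlyB <- ids[nA + seq_len(nB - nsh)]
    list(A = gene_set(paste0(prefix, "_A"), c(shared, onlyA)),
         B = gene_set(paste0(prefix, "_B"), c(shared, onlyB)))
  }
  with_seed(seed, list(
    up = make_pair(n_up_A, n_up_B, n_up_shared, "up"),
    down = make_pair(n_down_A, n_down_B, n_down_shared, "down")))
}
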