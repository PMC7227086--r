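# Degradome profiling, cis-cleavage validation and RACE clone tallying.

#' Construct a degradome 5'-end profile
#'
#' @param locus_id locus identifier.
#' @param counts per-position 5'-end counts on the sense strand (length =
#'   locus length).
#' @param total_mapped library size used as the RPKM denominator; default
#'   the sum of counts.
#' @return object of class `degradome_profile`.
#' @export
degradome_profile <- function(locus_id, counts, total_mapped = sum(counts)) {
  if (any(counts < 0)) stop("degradome counts must be non-negative")
  structure(list(locus_id = locus_id, counts = as.numeric(counts),
                 total_mapped = total_mapped), class = "degradome_profile")
}

#' @export
print.degradome_profile <- function(x, ...) {
  cat(sprintf("<degradome_profile> %s: %d positions, %g reads (total_mapped %g)\n",
              x$locus_id, length(x$counts), sum(x$counts), x$total_mapped))
  invisible(x)
}

#' Filter degradome signal upstream of the targeted region
#'
#' Zeroes counts at positions strictly upstream (smaller sense coordinate)
#' of the 5'-most predicted slice coordinate among the given sites; counts
#' at and downstream of that coordinate are untouched. This removes decay
#' signal that cannot derive from small-RNA-guided slicing at the sites.
#'
#' @param profile a [degradome_profile()].
#' @param sites target sites (data.frame with `slice_coord_0b`) or numeric
#'   slice coordinates.
#' @return the filtered profile. An empty site list returns the profile
#'   unchanged with a warning.
#' @export
filter_upstream <- function(profile, sites) {
  coords <- if (is.data.frame(sites)) sites$slice_coord_0b else sites
  if (length(coords) == 0L) {
    warning("no sites supplied; profile returned unchanged")
    return(profile)
  }
  cut <- min(coords)
  if (cut > 0L) profile$counts[seq_len(min(cut, length(profile$counts)))] <- 0
  profile
}

#' RPKM of a profile region
#'
#' RPKM = reads in region * 1e9 / (region length * total_mapped).
#'
#' @param profile a [degradome_profile()].
#' @param region 0-based half-open interval `c(start, end)`; default the
#'   whole locus.
#' @return numeric RPKM value.
#' @export
rpkm <- function(profile, region = c(0L, length(profile$counts))) {
  if (profile$total_mapped <= 0) stop("total_mapped must be > 0")
  start <- region[1]; end <- region[2]
  if (end <= start) stop("zero-length region")
  if (start < 0L || end > length(profile$counts))
    stop("region outside the locus")
  sum(profile$counts[(start + 1L):end]) * 1e9 /
    ((end - start) * profile$total_mapped)
}

#' Wilcoxon rank-sum enrichment test between two groups
#'
#' Two-sided Mann-Whitney test: exact enumeration when both groups have at
#' most 10 observations and there are no ties, otherwise the normal
#' approximation with tie and continuity correction. The path taken is
#' reported for reproducibility.
#'
#' @param groupA,groupB numeric vectors (e.g. per-gene RPKM values).
#' @param alternative test direction (default two-sided).
#' @return list with `statistic` (W), `p_value`, `method` ("exact" or
#'   "normal_approx").
#' @export
enrichment_test <- function(groupA, groupB, alternative = "two.sided") {
  if (length(groupA) == 0L || length(groupB) == 0L)
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(groupA, groupB)) > 0L
  exact <- !ties && length(groupA) <= 10L && length(groupB) <= 10L
  ht <- suppressWarnings(
    wilcox.test(groupA, groupB, alternative = alternative,
                exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "exact" else "normal_approx")
}

#' Tally RACE clones against predicted slice sites
#'
#' Each clone is assigned to the site with `|position - slice_coord| <=
#' tolerance`; the nearest site wins, ties going to the smaller coordinate.
#' Clones matching no site are counted as unassigned. Fractions are over
#' the total clone count.
#'
#' @param clones data.frame with `position_0b` (and optionally `locus_id`).
#' @param predicted_sites data.frame with `label`, `slice_coord_0b` and
#'   optionally `guide` (the guiding candidate name), sorted by coordinate.
#' @param tolerance maximum clone-to-site distance in nt (default 0).
#' @return list with `sites` (label, slice_coord_0b, guide, clone_count,
#'   clone_fraction), `n_unassigned`, `n_total`.
#' @export
race_tally <- function(clones, predicted_sites, tolerance = 0L) {
  sites <- predicted_sites[order(predicted_sites$slice_coord_0b), , drop = FALSE]
  n_total <- nrow(clones)
  counts <- integer(nrow(sites))
  unassigned <- 0L
  for (p in clones$position_0b) {
    d <- abs(p - sites$slice_coord_0b)
    j <- which.min(d)  # ties resolve to the smaller coordinate (sorted)
    if (length(j) && d[j] <= tolerance) counts[j] <- counts[j] + 1L
    else unassigned <- unassigned + 1L
  }
  out <- data.frame(
    label = sites$label, slice_coord_0b = sites$slice_coord_0b,
    guide = if ("guide" %in% names(sites)) sites$guide else NA_character_,
    clone_count = counts,
    clone_fraction = if (n_total > 0L) counts / n_total else rep(0, length(counts)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(sites = out, n_unassigned = unassigned, n_total = n_total)
}

#' Degradome peak signal-to-flank ratio
#'
#' Count at the slice coordinate divided by the mean count over the
#' surrounding `flank` positions on each side (the site itself excluded).
#' A zero flank mean with positive site signal yields `Inf`; a fully empty
#' neighbourhood yields `NA`.
#'
#' @param profile a [degradome_profile()].
#' @param slice_coord 0-based slice coordinate (or a site row with
#'   `slice_coord_0b`).
#' @param flank positions per side (>= 1).
#' @return numeric ratio.
#' @export
degradome_peak_check <- function(profile, slice_coord, flank = 10L) {
  if (is.list(slice_coord) || is.data.frame(slice_coord))
    slice_coord <- slice_coord$slice_coord_0b
  if (flank < 1L) stop("flank must be >= 1")
  L <- length(profile$counts)
  if (slice_coord < 0L || slice_coord >= L) stop("site outside the profile")
  idx <- setdiff(max(0L, slice_coord - flank):min(L - 1L, slice_coord + flank),
                 slice_coord)
  fl <- mean(profile$counts[idx + 1L])
  s <- profile$counts[slice_coord + 1L]
  if (fl == 0) {
    if (s > 0) Inf else NA_real_
  } else s / fl
}

#' Box-plot summary statistics of a group
#'
#' Median and quartiles use linear interpolation (quantile type 7);
#' whiskers extend 1.5 times the interquartile range beyond the box edges.
#'
#' @param values numeric vector.
#' @param group group label for the output row.
#' @return one-row data.frame: `group`, `median`, `q1`, `q3`,
#'   `lower_whisker`, `upper_whisker`, `n`.
#' @export
box_stats <- function(values, group = "group") {
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  data.frame(group = group, median = q[2], q1 = q[1], q3 = q[3],
             lower_whisker = q[1] - 1.5 * iqr,
             upper_whisker = q[3] + 1.5 * iqr,
             n = length(values), stringsAsFactors = FALSE)
}
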