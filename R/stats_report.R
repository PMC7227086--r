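# Gene-set overlap, enrichment statistics and summary tables.

#' Construct a gene set
#'
#' @param label set label, e.g. `"hypocotyl_down"`.
#' @param members character vector of gene identifiers; duplicates are
#'   removed with a warning.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(label, members) {
  members <- as.character(members)
  if (anyDuplicated(members)) {
    warning(sprintf("removed %d duplicate member(s) from '%s'",
                    sum(duplicated(members)), label))
    members <- unique(members)
  }
  structure(list(label = label, members = members), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s (%d genes)\n", x$label, length(x$members)))
  invisible(x)
}

as_members <- function(x) if (inherits(x, "gene_set")) x$members else as.character(x)

#' Venn overlap of two gene sets
#'
#' Percentages are 100 * |A ∩ B| / |A| (and / |B|), rounded to one decimal
#' half-away-from-zero, the convention of printed overlap percentages.
#' An empty set's percentage is `NA`.
#'
#' @param setA,setB [gene_set()]s or character vectors.
#' @return list with `n_A`, `n_B`, `n_intersect`, `pct_of_A`, `pct_of_B`.
#' @export
venn_overlap <- function(setA, setB) {
  a <- unique(as_members(setA)); b <- unique(as_members(setB))
  ni <- length(intersect(a, b))
  pct <- function(n) if (n == 0L) NA_real_ else round_half_away(100 * ni / n, 1L)
  list(n_A = length(a), n_B = length(b), n_intersect = ni,
       pct_of_A = pct(length(a)), pct_of_B = pct(length(b)))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by hypergeometric enumeration (every table at the
#' fixed margins with probability at most that of the observed table is
#' summed). The odds ratio is the sample value a*d / (b*c), with `Inf`
#' when b*c = 0 and a*d > 0 and `NaN` when both products are zero.
#'
#' @param a,b,c,d cell counts (rows: in set A / not; columns: in set B /
#'   not), or `a` may be a 2x2 matrix.
#' @return list with `odds_ratio`, `p_value`.
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    m <- a
  } else {
    m <- matrix(c(a, c, b, d), nrow = 2L)
  }
  if (any(m < 0)) stop("all cells must be non-negative")
  p <- fisher.test(m)$p.value
  ad <- m[1, 1] * m[2, 2]; bc <- m[1, 2] * m[2, 1]
  or <- if (bc == 0) { if (ad == 0) NaN else Inf } else ad / bc
  list(odds_ratio = or, p_value = p)
}

#' Row-standardised, cluster-ordered expression matrix
#'
#' Each row is scaled to mean 0 and (sample) standard deviation 1; rows
#' with zero variance are emitted as all-zero and flagged. Rows are
#' ordered by average-linkage hierarchical clustering on Euclidean
#' distance of the scaled values.
#'
#' @param mat numeric matrix (genes x conditions, >= 2 conditions) with
#'   rownames.
#' @return list with `z` (scaled matrix in cluster order), `order` (row
#'   permutation applied), `zero_variance` (named logical, input order).
#' @export
expression_matrix_summary <- function(mat) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat)) {
    bad <- which(!vapply(as.data.frame(mat), is.numeric, logical(1)))[1]
    stop(sprintf("non-numeric values in column %s", colnames(mat)[bad]))
  }
  if (ncol(mat) < 2L) stop("at least 2 conditions required")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("row", seq_len(nrow(mat)))
  s <- apply(mat, 1L, sd)
  zero <- s == 0
  z <- (mat - rowMeans(mat)) / ifelse(zero, 1, s)
  z[zero, ] <- 0
  ord <- if (nrow(z) > 2L) hclust(dist(z), method = "average")$order
         else seq_len(nrow(z))
  list(z = z[ord, , drop = FALSE], order = ord,
       zero_variance = stats::setNames(zero, rownames(mat)))
}
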