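# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# reverse complement without Biostrings
oracle_rc <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

# every exact occurrence of `read` in `seq`, both strands, via a naive
# window scan; returns data.frame(start_0b, strand)
oracle_map_one <- function(read, seq) {
  L <- nchar(read); W <- nchar(seq) - L + 1L
  if (W < 1L)
    return(data.frame(start_0b = integer(0), strand = character(0)))
  wins <- substring(seq, seq_len(W), seq_len(W) + L - 1L)
  fwd <- which(wins == read) - 1L
  rev <- which(wins == oracle_rc(read)) - 1L
  data.frame(start_0b = c(fwd, rev),
             strand = rep(c("+", "-"), c(length(fwd), length(rev))),
             stringsAsFactors = FALSE)
}

# per-window antiparallel pair classification for a guide on a transcript;
# returns data.frame(start_0b, mm, gu)
oracle_scan <- function(guide, seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  L <- nchar(guide); W <- nchar(seq) - L + 1L
  g <- strsplit(guide, "")[[1]]
  out <- data.frame(start_0b = integer(0), mm = integer(0), gu = integer(0))
  for (s in seq_len(max(0L, W))) {
    t <- rev(strsplit(substring(seq, s, s + L - 1L), "")[[1]])
    mm <- 0L; gu <- 0L
    for (i in seq_len(L)) {
      if (comp[[g[i]]] == t[i]) next
      if ((g[i] == "T" && t[i] == "G") || (g[i] == "G" && t[i] == "T"))
        gu <- gu + 1L
      else mm <- mm + 1L
    }
    out <- rbind(out, data.frame(start_0b = s - 1L, mm = mm, gu = gu))
  }
  out
}

# exact two-sided Wilcoxon rank-sum p by full enumeration (no ties)
oracle_wilcox_p <- function(a, b) {
  na <- length(a); N <- na + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(N, na)
  us <- colSums(matrix(seq_len(N)[sets], nrow = na)) - na * (na + 1) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# two-sided Fisher p by hypergeometric enumeration at fixed margins
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  lo <- max(0L, r1 + c1 - N); hi <- min(r1, c1)
  x <- lo:hi
  pr <- stats::dhyper(x, c1, N - c1, r1)
  p_obs <- stats::dhyper(a, c1, N - c1, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# independent windowed phasing score for one anchor residue: plain-loop
# reimplementation from the definition
oracle_phasing_score <- function(alignments, anchor, locus_len,
                                 len_range = c(20, 22), window = 8) {
  a <- alignments[alignments$length >= len_range[1] &
                    alignments$length <= len_range[2], , drop = FALSE]
  n_cyc <- (locus_len - anchor) %/% 21
  cc <- numeric(n_cyc)
  for (i in seq_len(nrow(a))) {
    eff <- if (a$strand[i] == "+") a$start_0b[i] else a$start_0b[i] + 2
    if (eff >= anchor && (eff - anchor) %% 21 == 0) {
      d <- (eff - anchor) %/% 21 + 1
      if (d <= n_cyc) cc[d] <- cc[d] + a$count[i]
    }
  }
  best <- 0
  if (n_cyc >= window) {
    for (w in seq_len(n_cyc - window + 1)) {
      win <- cc[w:(w + window - 1)]
      n <- sum(win > 0); k <- sum(win)
      p <- if (n > 2) (n - 2) * log(1 + k) else 0
      if (p > best) best <- p
    }
  }
  best
}

# standard two-frame simulation used across tests
sim_two_frame <- function(seed, ...) {
  cfg <- sim_config(seed = seed, ...)
  lc <- generate_locus(cfg)
  imp <- implant_target_sites(lc, cfg$guide_sequences,
                              gap = cfg$inter_site_gap,
                              start = cfg$site_start)
  sim <- simulate_phased_reads(imp$locus, imp$truth, cfg)
  list(config = cfg, locus = imp$locus, truth = sim$truth,
       library = sim$library)
}
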