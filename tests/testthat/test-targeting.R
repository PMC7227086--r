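embed_site <- function(guide, flank5 = 60, flank6 = 60) {
  seq <- paste0(rand_dna(flank5), revcomp(guide), rand_dna(flank6))
  list(tx = locus("tx", seq), start = flank5)
}

test_that("a perfect complementary site is found with zero mismatches", {
  set.seed(41)
  g <- c(miR = rand_dna(22))
  e <- embed_site(g)
  hits <- scan_mirna_targets(g, e$tx)
  hit <- hits[hits$start_0b == e$start, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$mismatches, 0)
  expect_equal(hit$gu_pairs, 0)
  expect_equal(hit$score, 0)
  expect_equal(hit$slice_coord_0b, e$start + 22 - 10)
})

test_that("mismatch and G:U budgets are enforced at their boundaries", {
  set.seed(42)
  g <- "ACCAGGACCAGGACCAGGACC"  # 21 nt, no T/G ambiguity at mutated spots
  site <- revcomp(g)
  mutate <- function(s, pos, to) { substr(s, pos, pos) <- to; s }
  # 4 mismatches: replace 4 site positions by the guide's own base there
  s4 <- site
  for (p in c(2, 6, 10, 14)) {
    old <- substring(s4, p, p)
    s4 <- mutate(s4, p, setdiff(c("A", "C"), old)[1])
  }
  tx4 <- locus("t4", paste0(rand_dna(50), s4, rand_dna(50)))
  expect_false(50 %in% scan_mirna_targets(c(g = g), tx4)$start_0b)

  # 0 mismatches, 2 G:U: turn two A:T pairs into G:T (target T -> G? no:
  # guide G vs target T). Put G in the guide means editing guide; instead
  # make target positions pairing guide T into G (guide T : target G = GU).
  gt <- "ATTAGTACCAGTACCATTACC"
  siteg <- revcomp(gt)
  tpos <- which(strsplit(gt, "")[[1]] == "T")[1:2]
  L <- nchar(gt)
  for (i in tpos) siteg <- mutate(siteg, L - i + 1, "G")
  txg <- locus("tg", paste0(rand_dna(50), siteg, rand_dna(50)))
  hits1 <- scan_mirna_targets(c(g = gt), txg, max_gu_bulge = 1)
  expect_false(50 %in% hits1$start_0b)
  hits2 <- scan_mirna_targets(c(g = gt), txg, max_gu_bulge = 2)
  h <- hits2[hits2$start_0b == 50, ]
  expect_equal(h$gu_pairs, 2)
  expect_equal(h$mismatches, 0)
})

test_that("phasiRNA scanning uses the stricter 2-mismatch budget", {
  set.seed(43)
  g <- rand_dna(21)
  site <- revcomp(g)
  mutate_mm <- function(s, positions) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    for (p in positions) {
      old <- substring(s, p, p)
      # choose a base that is neither the original (WC) nor creates G:U
      gpos <- nchar(s) - p + 1
      gch <- substring(g, gpos, gpos)
      bad <- c(old, if (gch == "T") "G", if (gch == "G") "T")
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), bad)[1]
    }
    s
  }
  s2 <- mutate_mm(site, c(3, 8))
  s3 <- mutate_mm(site, c(3, 8, 15))
  tx2 <- locus("a", paste0(rand_dna(40), s2, rand_dna(40)))
  tx3 <- locus("b", paste0(rand_dna(40), s3, rand_dna(40)))
  h2 <- scan_phasirna_targets(c(p1 = g), tx2)
  expect_true(40 %in% h2$start_0b)
  expect_equal(h2$mismatches[h2$start_0b == 40], 2)
  expect_false(40 %in% scan_phasirna_targets(c(p1 = g), tx3)$start_0b)
})

test_that("a called phasiRNA reports a cis site on its own source locus", {
  s <- sim_two_frame(44, noise_fraction = 0)
  al <- map_reads(s$library, s$locus)
  fr <- phasing_frame(s$locus$id, s$truth$frame_anchors[1], "PF1")
  cand <- call_phasirnas(fr, al, min_count = 1, locus = s$locus)
  cand <- cand[cand$strand == "-", ][1, ]
  hits <- scan_phasirna_targets(stats::setNames(cand$sequence, cand$name),
                                s$locus)
  expect_true(nrow(hits) >= 1)
  expect_true(all(hits$slice_coord_0b >= 0 &
                    hits$slice_coord_0b < nchar(s$locus$sequence)))
  # the antisense candidate's perfect cis site is its own duplex footprint
  expect_true(cand$start_0b %in% hits$start_0b)
})

test_that("slice coordinates implement the 10/11 rule for both guide lengths", {
  expect_equal(predicted_slice_coord(list(start_0b = 100, length = 21)), 111)
  expect_equal(predicted_slice_coord(list(start_0b = 100, length = 22)), 112)
  expect_equal(
    predicted_slice_coord(list(start_0b = 133, length = 21)) -
      predicted_slice_coord(list(start_0b = 100, length = 21)), 33)
})

test_that("slice coordinates equal the frame anchors recorded by the generator", {
  s <- sim_two_frame(45)
  hits <- scan_mirna_targets(s$config$guide_sequences, s$locus,
                             max_mismatch = 0, max_gu_bulge = 0)
  expect_setequal(hits$slice_coord_0b, s$truth$frame_anchors)
  expect_setequal(predicted_slice_coord(hits), s$truth$frame_anchors)
})

test_that("duplex scoring follows the penalty and pseudo-energy tables", {
  gc21 <- paste(rep("GC", 11), collapse = "")
  gc21 <- substring(gc21, 1, 21)
  perfect <- duplex_score(gc21, revcomp(gc21))
  expect_equal(perfect$score, 0)
  expect_equal(perfect$energy, -63)

  set.seed(46)
  g <- "ACCAGCACCAGCACCAGCACC"
  site <- revcomp(g)
  # mismatch at guide position 20 (outside the doubled 2-13 region)
  s <- site; substr(s, 2, 2) <- "C"   # window pos 2 pairs guide nt 20
  d <- duplex_score(g, s)
  expect_equal(d$mismatches, 1)
  expect_equal(d$score, 1.0)
  # G:U at guide position 5 (inside 2-13): guide T pairs target G
  gt <- "ACCATCACCAGCACCAGCACC"  # T at guide pos 5
  sg <- revcomp(gt); substr(sg, 21 - 5 + 1, 21 - 5 + 1) <- "G"
  d2 <- duplex_score(gt, sg)
  expect_equal(d2$gu_pairs, 1)
  expect_equal(d2$mismatches, 0)
  expect_equal(d2$score, 1.0)
  expect_error(duplex_score("ACGT", "ACGTA"), "equal length")
})

test_that("adding a mismatch never decreases score or energy", {
  set.seed(47)
  for (i in 1:20) {
    g <- rand_dna(21)
    win <- revcomp(g)
    p <- sample(21, 1)
    gpos <- 21 - p + 1
    gch <- substring(g, gpos, gpos)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    bad <- c(comp[[gch]], if (gch == "T") "G", if (gch == "G") "T")
    repl <- setdiff(c("A", "C", "G", "T"), bad)
    if (!length(repl)) next
    win2 <- win; substr(win2, p, p) <- repl[1]
    d1 <- duplex_score(g, win); d2 <- duplex_score(g, win2)
    expect_gte(d2$score, d1$score)
    expect_gte(d2$energy, d1$energy)
  }
})

test_that("a guide does not hit its own sequence on the sense strand", {
  set.seed(48)
  g <- "ACCAGGTTCAGGACCATGACC"
  tx <- locus("t", paste0(rand_dna(40), g, rand_dna(40)))
  hits <- scan_mirna_targets(c(g = g), tx, max_mismatch = 0, max_gu_bulge = 0)
  expect_false(40 %in% hits$start_0b)
})

test_that("window classification agrees with the per-pair oracle", {
  set.seed(49)
  for (rep in 1:15) {
    g <- rand_dna(sample(20:22, 1))
    tx <- rand_dna(80)
    # implant a near-match so hits exist
    s <- sample(50, 1)
    substr(tx, s, s + nchar(g) - 1) <- revcomp(g)
    orc <- oracle_scan(g, tx)
    hits <- scan_mirna_targets(c(g = g), locus("t", tx),
                               max_mismatch = nchar(g), max_gu_bulge = Inf)
    expect_equal(nrow(hits), nrow(orc))
    expect_equal(hits$mismatches, orc$mm)
    expect_equal(hits$gu_pairs, orc$gu)
  }
})
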