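test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 11)
  expect_identical(generate_locus(cfg)$sequence, generate_locus(cfg)$sequence)
  s1 <- sim_two_frame(11); s2 <- sim_two_frame(11)
  expect_identical(s1$library, s2$library)
  expect_identical(s1$truth$duplex_reads, s2$truth$duplex_reads)
  expect_identical(simulate_degradome(s1$locus, s1$truth, cfg)$counts,
                   simulate_degradome(s2$locus, s2$truth, cfg)$counts)
  expect_identical(
    simulate_race_clones(s1$truth, cfg, sites = c(100, 200, 300, 400)),
    simulate_race_clones(s2$truth, cfg, sites = c(100, 200, 300, 400)))
})

test_that("locus composition honours the GC model and its boundaries", {
  at_only <- generate_locus(sim_config(seed = 2, gc_fraction = 0))
  expect_true(grepl("^[AT]+$", at_only$sequence))
  gc_only <- generate_locus(sim_config(seed = 2, gc_fraction = 1))
  expect_true(grepl("^[GC]+$", gc_only$sequence))
  lc <- generate_locus(sim_config(seed = 3, gc_fraction = 0.7,
                                  locus_length = 5000))
  gc <- mean(strsplit(lc$sequence, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.7), 0.03)
  expect_equal(nchar(lc$sequence), 5000)
})

test_that("locus geometry checks admit tight fits and reject impossible ones", {
  g2 <- c(a = rand_dna(21), b = rand_dna(21))
  # two 21-nt guides + 12-nt gap = 54 nt fits in a 100-nt locus
  cfg <- sim_config(seed = 4, locus_length = 100, guide_sequences = g2,
                    site_start = 10)
  expect_s3_class(generate_locus(cfg), "locus")
  expect_error(generate_locus(sim_config(seed = 4, locus_length = 60,
                                         guide_sequences = g2,
                                         site_start = 10)),
               "degenerate geometry")
})

test_that("implantation writes exact reverse complements at the stated coordinates", {
  set.seed(5)
  lc <- locus("L", rand_dna(400))
  g <- rand_dna(21)
  one <- implant_target_sites(lc, c(g1 = g), start = 100)
  expect_equal(one$truth$site_coords$start_0b, 100)
  expect_equal(one$truth$site_coords$end_0b, 121)
  expect_identical(substring(one$locus$sequence, 101, 121), revcomp(g))

  two <- implant_target_sites(lc, c(a = rand_dna(21), b = rand_dna(21)),
                              gap = 12, start = 100)
  expect_equal(two$truth$site_coords$start_0b, c(100, 133))
  expect_equal(diff(two$truth$site_coords$slice_coord_0b), 33)
  expect_equal(33 %% 21, 12)

  abut <- implant_target_sites(lc, c(a = rand_dna(21), b = rand_dna(21)),
                               gap = 0, start = 100)
  expect_equal(abut$truth$site_coords$start_0b[2], 121)

  expect_error(implant_target_sites(lc, c(g1 = rand_dna(21)), start = 390),
               "geometry")
})

test_that("noise-free phased reads sit exactly on the register with the 2-nt overhang", {
  s <- sim_two_frame(6, noise_fraction = 0, duplex_dispersion = Inf)
  dr <- s$truth$duplex_reads
  anchors <- s$truth$frame_anchors
  for (f in seq_along(anchors)) {
    sn <- dr[dr$frame == f & dr$strand == "+", ]
    as <- dr[dr$frame == f & dr$strand == "-", ]
    expect_true(all((sn$start_0b - anchors[f]) %% 21 == 0))
    expect_true(all((as$start_0b + 2 - anchors[f]) %% 21 == 0))
    expect_equal(as$start_0b, sn$start_0b - 2)
  }
  expect_equal(nrow(s$truth$noise_reads), 0)
  expect_equal(total_mapped(s$library), sum(dr$count))
})

test_that("fixed-count single-frame emission places 5' ends at c, c+21, ...", {
  set.seed(7)
  lc <- locus("L", rand_dna(400))
  imp <- implant_target_sites(lc, c(g = rand_dna(21)), start = 50)
  cfg <- sim_config(seed = 7, locus_length = 400, n_duplexes_per_frame = 8,
                    duplex_mean_count = 1e6, duplex_dispersion = Inf,
                    noise_fraction = 0)
  # huge mean guarantees every duplex strand is emitted
  sim <- simulate_phased_reads(imp$locus, imp$truth, cfg)
  c0 <- imp$truth$frame_anchors[1]
  sense <- sim$truth$duplex_reads[sim$truth$duplex_reads$strand == "+", ]
  expect_equal(sort(sense$start_0b), c0 + 21 * (0:7))
})

test_that("all-noise libraries contain only noise and total counts balance", {
  s <- sim_two_frame(8, noise_fraction = 1)
  expect_true(all(s$truth$duplex_reads$count == 0))
  expect_gt(nrow(s$truth$noise_reads), 0)
  expect_true(all(s$truth$noise_reads$length >= 18 &
                    s$truth$noise_reads$length <= 29))
  expect_equal(s$truth$library_total,
               sum(s$truth$duplex_reads$count) + nrow(s$truth$noise_reads))
  expect_equal(total_mapped(s$library), s$truth$library_total)
})

test_that("RACE clone draws honour the site probabilities", {
  s <- sim_two_frame(9)
  cfg <- s$config
  sites <- c(111, 144, 250, 300)
  cl <- simulate_race_clones(s$truth, cfg, sites = sites)
  expect_equal(nrow(cl), 35)
  expect_true(all(cl$position_0b %in% sites))

  none <- simulate_race_clones(s$truth, sim_config(seed = 9, n_race_clones = 0),
                               sites = sites)
  expect_equal(nrow(none), 0)

  all_one <- simulate_race_clones(
    s$truth, sim_config(seed = 9, race_site_probs = c(1, 0, 0, 0)),
    sites = sites)
  expect_true(all(all_one$position_0b == sites[1]))

  expect_error(simulate_race_clones(s$truth, cfg, sites = c(1, 2)),
               "length")
})

test_that("RACE tallies converge to the site probabilities (chi-square GOF)", {
  s <- sim_two_frame(10)
  cfg <- sim_config(seed = 10, n_race_clones = 1e5)
  sites <- c(111, 144, 250, 300)
  cl <- simulate_race_clones(s$truth, cfg, sites = sites)
  obs <- table(factor(cl$position_0b, levels = sites))
  gof <- suppressWarnings(stats::chisq.test(obs, p = cfg$race_site_probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("gene-set simulation honours exact overlap structure", {
  tb <- simulate_deg_tables(92, 60, 38, 67, 70, 65, seed = 1)
  expect_equal(length(tb$up$A$members), 92)
  expect_equal(length(tb$up$B$members), 60)
  expect_equal(length(intersect(tb$up$A$members, tb$up$B$members)), 38)
  expect_equal(length(intersect(tb$down$A$members, tb$down$B$members)), 65)

  same <- simulate_deg_tables(67, 67, 67, 5, 5, 0, seed = 1)
  expect_setequal(same$up$A$members, same$up$B$members)
  expect_length(intersect(same$down$A$members, same$down$B$members), 0)

  expect_error(simulate_deg_tables(5, 5, 6, 1, 1, 0), "shared")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(noise_fraction = 1.2), "noise_fraction")
  expect_error(sim_config(race_site_probs = c(0.5, 0.4)), "sum to 1")
  expect_error(sim_config(guide_sequences = c(g = rand_dna(20))),
               "21 or 22")
  expect_error(sim_config(inter_site_gap = -1), "inter_site_gap")
  expect_error(sim_config(duplex_dispersion = 0), "dispersion")
  # RNA-alphabet guides are normalised to DNA
  cfg <- sim_config(guide_sequences = c(g = paste(rep("U", 21), collapse = "")))
  expect_identical(cfg$guide_sequences[["g"]],
                   paste(rep("T", 21), collapse = ""))
})
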