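test_that("palindromic site assembly is reverse-complement + spacer + half-site", {
  expect_identical(make_palindromic_site("GTGAAA", "ACGT"), "TTTCACACGTGTGAAA")
  expect_identical(make_palindromic_site("AAAAAA", "TTTT"), "TTTTTTTTTTAAAAAA")
  for (sp in c("ACGT", "GGGG", "TACG")) {
    s <- make_palindromic_site("GTGAAA", sp)
    expect_identical(substr(s, 11, 16), "GTGAAA")
    expect_identical(nchar(s), 16L)
  }
  expect_error(make_palindromic_site("GTGAA", "ACGT"), "6-mer")
  expect_error(make_palindromic_site("GTGAAA", "ACGTA"), "4-mer")
  expect_error(make_palindromic_site("GTGAAX", "ACGT"))
})

test_that("build_genome plants sites at their coordinates, deterministically", {
  site_seq <- make_palindromic_site("GTGAAA", "ATAT")
  g <- build_genome(10000, planted_sites(5000, site_seq, kd = 30), seed = 3L)
  expect_identical(substr(g$sequence, 5001, 5016), site_seq)
  expect_identical(nchar(g$sequence), 10000L)

  g1 <- build_genome(100, seed = 7L)
  g2 <- build_genome(100, seed = 7L)
  expect_identical(g1$sequence, g2$sequence)
  expect_false(identical(g1$sequence, build_genome(100, seed = 8L)$sequence))

  overlapping <- planted_sites(c(100, 110),
                               c(strrep("A", 16), strrep("C", 16)),
                               kd = c(10, 10), label = c("sA", "sB"))
  expect_error(build_genome(1000, overlapping, seed = 1L), "sA.*sB")
  past_end <- planted_sites(995, strrep("A", 16), kd = 10, label = "sEnd")
  expect_error(build_genome(1000, past_end, seed = 1L, circular = FALSE),
               "sEnd")
  # on a circular genome the same site wraps legally
  gw <- build_genome(1000, past_end, seed = 1L, circular = TRUE)
  expect_identical(substr(gw$sequence, 996, 1000), strrep("A", 5))
  expect_identical(substr(gw$sequence, 1, 11), strrep("A", 11))
})

test_that("occupancy is nucleation over the site plus linear flank decay, max-combined", {
  site <- planted_sites(500, strrep("A", 16), kd = 10)
  occ0 <- simulate_occupancy(1000, site, spreading = 0, amplitudes = 1,
                             background = 0)
  expect_equal(which(occ0 == 1) - 1, 500:515)
  expect_true(all(occ0[-(501:516)] == 0))

  mid <- planted_sites(2000, strrep("A", 16), kd = 10)
  occ <- simulate_occupancy(5000, mid, spreading = 1000, amplitudes = 1,
                            background = 0)
  support <- which(occ > 0)
  expect_identical(length(support), 16L + 2L * 1000L)
  expect_identical(support, min(support):max(support))
  # matches the direct per-base enumeration
  expect_equal(as.numeric(occ),
               oracle_single_site_occupancy(5000, 2000, 16, 1000, 1, 0))
  # a flank wrapping the origin of a circular genome keeps the same support size
  occw <- simulate_occupancy(5000, site, spreading = 1000, amplitudes = 1,
                             background = 0, circular = TRUE)
  expect_identical(sum(occw > 0), 16L + 2L * 1000L)
  expect_gt(occw[5000], 0)  # wrapped flank
  occl <- simulate_occupancy(5000, site, spreading = 1000, amplitudes = 1,
                             background = 0, circular = FALSE)
  expect_equal(as.numeric(occl),
               oracle_single_site_occupancy(5000, 500, 16, 1000, 1, 0))

  # overlapping flanks combine by maximum
  two <- planted_sites(c(500, 616), c(strrep("A", 16), strrep("C", 16)),
                       kd = c(10, 10))
  occ_a <- simulate_occupancy(2000, two[1, ], spreading = 300, amplitudes = 1,
                              background = 0)
  occ_b <- simulate_occupancy(2000, two[2, ], spreading = 300,
                              amplitudes = 0.6, background = 0)
  occ_ab <- simulate_occupancy(2000, two, spreading = 300,
                               amplitudes = c(1, 0.6), background = 0)
  expect_equal(as.numeric(occ_ab), pmax(as.numeric(occ_a), as.numeric(occ_b)))

  expect_error(simulate_occupancy(1000, site, amplitudes = 0.5,
                                  background = 0.6), "below")
})

test_that("ChIP fragment simulator retains by mean occupancy and is seed-deterministic", {
  occ1 <- rep(1, 2000)
  fr <- simulate_chip_fragments(occ1, 500, frag_len_fixed(100), seed = 2L)
  expect_identical(nrow(fr), 500L)  # acceptance probability 1: no shortfall

  # nucleation-only: zero acceptance off-site, so every fragment overlaps it
  site <- planted_sites(1000, strrep("A", 16), kd = 10)
  occ <- simulate_occupancy(4000, site, spreading = 0, amplitudes = 1,
                            background = 0, circular = FALSE)
  fr2 <- simulate_chip_fragments(occ, 300, frag_len_fixed(208), seed = 3L,
                                 circular = FALSE)
  expect_true(all(fr2$start < 1016 & fr2$start + fr2$length > 1000))

  expect_identical(simulate_chip_fragments(occ, 100, seed = 9L, circular = FALSE),
                   simulate_chip_fragments(occ, 100, seed = 9L, circular = FALSE))
  expect_error(simulate_chip_fragments(rep(0, 100), 10), "identically zero")
})

test_that("retained ChIP fragment midpoints are symmetric about an isolated site", {
  site <- planted_sites(5000, strrep("A", 16), kd = 10)
  occ <- simulate_occupancy(10000, site, spreading = 800, amplitudes = 1,
                            background = 0)
  fr <- simulate_chip_fragments(occ, 50000, frag_len_fixed(150), seed = 4L)
  mid <- fr$start + fr$length / 2
  center <- 5000 + 8
  se <- stats::sd(mid) / sqrt(length(mid))
  expect_lt(abs(mean(mid) - center), 3 * se)
})

test_that("IDAP retention follows containment and the 1:1 isotherm", {
  g <- tiny_site_genome(kd = 320)  # theta = 0.5 at 320 nM
  fr <- simulate_idap_fragments(g, protein_conc = 320, n = 2000, seed = 6L)
  # containment is exhaustively checkable: every retained fragment holds the site
  expect_true(all(fr$start <= 5000 & fr$start + fr$length >= 5016))
  expect_identical(fr, simulate_idap_fragments(g, 320, 2000, seed = 6L))

  # retention-probability ratio between a strong and a weak site:
  # theta(1 nM) / theta(1000 nM) at 320 nM = (320/321)/(320/1320)
  two <- build_genome(40000,
                      planted_sites(c(10000, 30000),
                                    c(make_palindromic_site("GTGAAA", "ACGT"),
                                      make_palindromic_site("GTGAAA", "ATAT")),
                                    kd = c(1, 1000)),
                      seed = 2L, circular = TRUE, with_sequence = FALSE)
  fr2 <- simulate_idap_fragments(two, protein_conc = 320, n = 30000,
                                 frag_length_sampler = frag_len_fixed(300),
                                 seed = 7L)
  n_strong <- sum(fr2$start <= 10000 & fr2$start + fr2$length >= 10016)
  n_weak <- sum(fr2$start <= 30000 & fr2$start + fr2$length >= 30016)
  expected <- (320 / 321) / (320 / 1320)
  obs <- n_strong / n_weak
  se <- obs * sqrt(1 / n_strong + 1 / n_weak)
  expect_lt(abs(obs - expected), 3 * se)

  expect_error(simulate_idap_fragments(
    build_genome(1000, seed = 1L, with_sequence = FALSE), 320, 10),
    "no planted sites")
})

test_that("transposon insertions follow the fitness landscape", {
  # uniform landscape: per-10-kb-bin counts within 4 sd of the multinomial mean
  lib <- simulate_tn_library(rep(1, 1e5), 1e5, seed = 3L)
  bins <- bin_insertions(lib, 10000)
  mu <- 1e5 * (10000 / 1e5)
  sdv <- sqrt(1e5 * (10000 / 1e5) * (1 - 10000 / 1e5))
  expect_true(all(abs(bins$counts - mu) < 4 * sdv))
  expect_identical(sum(bins$counts), 1e5)

  # support restriction: zero weight outside one window
  w <- rep(0, 1e5); w[20001:30000] <- 1
  lib2 <- simulate_tn_library(w, 5000, seed = 4L)
  expect_true(all(lib2$positions >= 20000 & lib2$positions < 30000))

  # 10x plateau: inside/outside mean bin-count ratio ~ 10
  lsc <- fitness_landscape(1e5, zone_center = 50000, zone_width = 30000,
                           plateau = 10, baseline = 1)
  lib3 <- simulate_tn_library(lsc, 2e5, seed = 5L)
  b3 <- bin_insertions(lib3, 10000)
  inside <- b3$bin_starts %in% c(40000, 50000)      # bins fully in the zone
  outside <- b3$bin_starts %in% c(0, 10000, 20000,  # bins fully outside
                                  70000, 80000, 90000)
  ratio <- mean(b3$counts[inside]) / mean(b3$counts[outside])
  expect_lt(abs(ratio - 10) / 10, 0.1)

  expect_error(simulate_tn_library(rep(0, 100), 10), "identically zero")

  # goodness of fit to the landscape proportions on a 10-bin toy landscape
  w10 <- rep(c(1, 2, 5, 1, 3, 1, 8, 1, 2, 1), each = 10)
  lib4 <- simulate_tn_library(w10, 1e5, seed = 6L)
  counts <- bin_insertions(lib4, 10)$counts
  gof <- stats::chisq.test(counts, p = tapply(w10, rep(1:10, each = 10), sum) / sum(w10))
  expect_gt(gof$p.value, 0.001)
})

test_that("SPR titration simulator follows the isotherm with additive noise", {
  t1 <- simulate_spr_titration(50, 200, concentrations = 50, noise_sd = 0)
  expect_equal(t1$response_RU, 100)  # c = kd -> rmax / 2
  t2 <- simulate_spr_titration(50, 200, concentrations = 50e6, noise_sd = 0)
  expect_lt(abs(t2$response_RU - 200) / 200, 1e-5)  # saturation
  expect_identical(spr_default_concentrations(),
                   c(6.25, 12.5, 25, 50, 100, 200, 400, 600, 800))
  t3 <- simulate_spr_titration(30, 100, noise_sd = 2, seed = 11L)
  expect_identical(t3, simulate_spr_titration(30, 100, noise_sd = 2, seed = 11L))
  expect_error(simulate_spr_titration(-1, 100), "kd")
})
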