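test_that("enriched-region calling finds, merges and filters runs", {
  v <- rep(0, 1000); v[101:300] <- 10
  tr <- coverage_track(v, units = "fold_enrichment", genome_length = 1000,
                       circular = FALSE)
  reg <- call_enriched_regions(tr, threshold = 2)
  expect_equal(reg$start, 100)
  expect_equal(reg$end, 300)
  expect_equal(reg$max_signal, 10)

  v2 <- rep(0, 1000); v2[101:200] <- 5; v2[251:350] <- 5
  tr2 <- coverage_track(v2, units = "fold_enrichment", genome_length = 1000,
                        circular = FALSE)
  expect_identical(nrow(call_enriched_regions(tr2, 2, min_run = 50, merge_gap = 100)), 1L)
  expect_identical(nrow(call_enriched_regions(tr2, 2, min_run = 50, merge_gap = 10)), 2L)

  low <- coverage_track(rep(1, 500), units = "fold_enrichment",
                        genome_length = 500, circular = FALSE)
  expect_identical(nrow(call_enriched_regions(low, 2)), 0L)

  # a region spanning the origin of a circular genome is reported wrapped
  v3 <- rep(0, 1000); v3[c(1:150, 901:1000)] <- 4
  tr3 <- coverage_track(v3, units = "fold_enrichment", genome_length = 1000,
                        circular = TRUE)
  reg3 <- call_enriched_regions(tr3, 2)
  expect_identical(nrow(reg3), 1L)
  expect_equal(reg3$width, 250)
  expect_equal(reg3$start, 900)
  expect_equal(reg3$end, 1150)
})

test_that("region calling is idempotent on its own indicator track", {
  v <- rep(0, 2000); v[301:800] <- 3; v[1201:1500] <- 2.5
  tr <- coverage_track(v, units = "fold_enrichment", genome_length = 2000,
                       circular = FALSE)
  reg <- call_enriched_regions(tr, 2, min_run = 100, merge_gap = 50)
  ind <- rep(0, 2000)
  for (i in seq_len(nrow(reg))) ind[(reg$start[i] + 1):reg$end[i]] <- 1
  tri <- coverage_track(ind, units = "fold_enrichment", genome_length = 2000,
                        circular = FALSE)
  reg2 <- call_enriched_regions(tri, 0.5, min_run = 100, merge_gap = 50)
  expect_equal(reg2$start, reg$start)
  expect_equal(reg2$end, reg$end)
})

test_that("spreading extent is the union length of anchor-covering regions", {
  reg <- data.frame(start = 4000, end = 6000, width = 2000)
  expect_equal(spreading_extent(reg, 5000, 1e6), 2000)
  expect_error(spreading_extent(reg, 9000, 1e6),
               class = "parbseq_undefined_extent")
  # wrapped region covers an anchor near the origin
  regw <- data.frame(start = 990, end = 1020, width = 30)
  expect_equal(spreading_extent(regw, 5, 1000), 30)
})

test_that("extent and width are invariant under joint rescaling of track and threshold", {
  v <- rep(0.5, 3000); v[1001:1800] <- 6
  tr <- coverage_track(v, units = "fold_enrichment", genome_length = 3000,
                       circular = FALSE)
  k <- 13
  trk <- coverage_track(v * k, units = "fold_enrichment", genome_length = 3000,
                        circular = FALSE)
  r1 <- call_enriched_regions(tr, 2)
  r2 <- call_enriched_regions(trk, 2 * k)
  expect_equal(spreading_extent(r1, 1400, 3000),
               spreading_extent(r2, 1400, 3000))
  expect_equal(peak_width(tr, 1400, background = 1),
               peak_width(trk, 1400, background = k))
})

test_that("peak width is the above-background support run containing the summit", {
  tri <- coverage_track(c(rep(0, 50), 51 - abs(-49:50), rep(0, 50)),
                        genome_length = 200, circular = FALSE)
  expect_equal(peak_width(tri, 100, background = 0), 100)
  expect_error(peak_width(tri, 100, background = 1000), "not above background")

  res <- study_nucleation_peak_width(seed = 2L)
  expect_equal(res$width, 2 * 208 - 16)
})

test_that("peak asymmetry compares flank areas and flags degenerate cases", {
  v <- rep(0, 4000)
  v[1001:1990] <- 2  # left flank of a site at [1990, 2010)
  v[2011:2510] <- 2  # right flank, half the area
  tr <- coverage_track(v, genome_length = 4000, circular = FALSE)
  expect_equal(peak_asymmetry(tr, 1990, 2010, flank = 1000), 990 / 500)

  v2 <- rep(0, 4000); v2[1001:1990] <- 2
  tr2 <- coverage_track(v2, genome_length = 4000, circular = FALSE)
  expect_error(peak_asymmetry(tr2, 1990, 2010, flank = 1000),
               class = "parbseq_undefined_asymmetry")
})

test_that("symmetric simulated spreading gives asymmetry near one", {
  site <- planted_sites(20000, strrep("A", 16), kd = 10)
  occ <- simulate_occupancy(40000, site, spreading = 2000, amplitudes = 1,
                            background = 0)
  fr <- simulate_chip_fragments(occ, 1e5, seed = 5L)
  tr <- fragment_coverage(fr, 40000)
  a <- peak_asymmetry(tr, 20000, 20016, flank = 5000)
  expect_lt(abs(a - 1), 0.05)
})

test_that("enrichment ratio over a region recovers scale factors", {
  b <- coverage_track(c(1, 2, 3, 4), units = "RPBPM", genome_length = 4)
  a <- coverage_track(5 * c(1, 2, 3, 4), units = "RPBPM", genome_length = 4)
  expect_equal(enrichment_ratio(a, b, c(0, 4)), 5)
  expect_equal(enrichment_ratio(b, b, c(1, 3)), 1)
  z <- coverage_track(c(0, 0, 0, 0), units = "RPBPM", genome_length = 4)
  expect_error(enrichment_ratio(a, z, c(0, 4)),
               class = "parbseq_undefined_ratio")
  raw <- coverage_track(c(1, 2, 3, 4), units = "raw", genome_length = 4)
  expect_error(enrichment_ratio(a, raw, c(0, 4)), "units")
})

test_that("recovered extent grows monotonically with the spreading parameter", {
  site <- planted_sites(100000, strrep("A", 16), kd = 10)
  extents <- vapply(c(250, 500, 1000, 1500, 2000), function(s) {
    occ <- simulate_occupancy(2e5, site, spreading = s, amplitudes = 1,
                              background = 0.02)
    chip <- simulate_chip_fragments(occ, 5e4, seed = 31L)
    inp <- simulate_input_fragments(2e5, 5e4, seed = 32L)
    fe <- fold_enrichment(normalize_rpbpm(fragment_coverage(chip, 2e5)),
                          normalize_rpbpm(fragment_coverage(inp, 2e5)))
    reg <- call_enriched_regions(fe, 2, min_run = 100, merge_gap = 500,
                                 smooth = 201)
    spreading_extent(reg, 100008, 2e5)
  }, numeric(1))
  expect_true(all(diff(extents) > 0))
  # and each recovered extent is close to its generator's occupied span
  expect_lt(abs(extents[5] - (16 + 2 * 2000)) / (16 + 2 * 2000), 0.1)
})
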