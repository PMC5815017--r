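# The reproducible desk-scale studies. Each function encodes one simulated
# experiment's full conditions (genome geometry, library sizes, occupancy
# background, thresholds) and runs the corresponding analysis end to end.
# The analysis/ scripts, the test suite and scripts/acceptance.R all call
# these, so the conditions are defined exactly once.

#' Exhaustive-fragment site call at nucleotide resolution
#'
#' Plants one palindromic 16-bp site on a linear toy genome, enumerates
#' *every* fragment of the given length range that fully contains it,
#' computes strand-specific 5'-end counts and pairs the summits with the
#' edge-directed tie-breaks. The deterministic analogue of an
#' affinity-purification experiment sequenced to saturation: the called
#' interval should be exactly the planted site.
#'
#' @param genome_length toy genome length in bp.
#' @param site_start 0-based site start.
#' @param len_range fragment length range (inclusive).
#' @return A list: `calls` (one-row call table), `n_fragments`, `genome`.
#' @export
study_exhaustive_site_call <- function(genome_length = 10000,
                                       site_start = 5000,
                                       len_range = c(50, 200)) {
  site <- planted_sites(site_start,
                        make_palindromic_site("GTGAAA", "ACGT"), kd = 30)
  genome <- build_genome(genome_length, site, seed = 5L, circular = FALSE)
  w <- site$width
  grid <- expand.grid(length = len_range[1]:len_range[2],
                      start = 0:(genome_length - 1))
  keep <- grid$start <= site_start &
    grid$start + grid$length >= site_start + w
  fragments <- data.frame(start = grid$start[keep],
                          length = grid$length[keep], source = "idap")
  ends <- strand_end_counts(fragments, genome_length, circular = FALSE)
  us <- find_summits(ends$upper, min_height = 1, tie_break = "rightmost")
  ls <- find_summits(ends$lower, min_height = 1, tie_break = "leftmost")
  calls <- pair_summits(us, ls, min_gap = 8, max_gap = 40,
                        genome_length = genome_length, circular = FALSE)
  list(calls = calls, n_fragments = nrow(fragments), genome = genome)
}

#' Seven-site recovery by simulated affinity purification
#'
#' Simulates an IDAP experiment on the default seven-site toy genome at the
#' standard protein concentration (320 nM) with a bead-only control, and runs
#' the full caller. Conditions: 200,000 retained sample fragments (uniform
#' 200-500 bp), background (site-free) retention probability 2e-4, 50,000
#' control fragments.
#'
#' @param seed integer seed.
#' @param n retained sample fragments.
#' @return A list: `calls`, `genome`, `recovered` (logical per planted site:
#'   overlapped by a call), `exact` (call interval equals the planted
#'   interval).
#' @export
study_seven_site_idap <- function(seed = 1L, n = 2e5) {
  genome <- toy_genome(101L)
  idap <- simulate_idap_fragments(genome, protein_conc = 320, n = n,
                                  background_prob = 2e-4, seed = seed)
  control <- simulate_input_fragments(genome$length, 5e4,
                                      frag_len_uniform(200, 500),
                                      seed = seed + 1L, source = "control")
  calls <- call_sites(idap, control, genome)
  sites <- genome$sites
  covered <- function(i) {
    any(calls$site_start <= sites$start[i] &
          calls$site_end >= sites$start[i] + sites$width[i] - 1)
  }
  exact <- function(i) {
    any(calls$site_start == sites$start[i] &
          calls$site_end == sites$start[i] + sites$width[i] - 1)
  }
  list(calls = calls, genome = genome,
       recovered = vapply(seq_len(nrow(sites)), covered, logical(1)),
       exact = vapply(seq_len(nrow(sites)), exact, logical(1)))
}

#' Nucleation-only peak width from containment coverage
#'
#' A site-specific (non-spreading) binder probed with fragments of fixed
#' length L that fully contain the w-bp site gives a coverage peak of support
#' width 2L - w. With L = 208 and w = 16 this is the 400-bp peak width
#' characteristic of nucleation without spreading.
#'
#' @param seed integer seed.
#' @param frag_len fixed fragment length in bp.
#' @param n retained fragments (enough to saturate every admissible start).
#' @return A list: `width` (bp), `track`, `site_start`.
#' @export
study_nucleation_peak_width <- function(seed = 1L, frag_len = 208, n = 5000) {
  site_start <- 5000
  site <- planted_sites(site_start,
                        make_palindromic_site("GTGAAA", "ACGT"), kd = 1)
  genome <- build_genome(10000, site, seed = 5L, circular = FALSE,
                         with_sequence = FALSE)
  frags <- simulate_idap_fragments(genome, protein_conc = 1e6, n = n,
                                   frag_length_sampler = frag_len_fixed(frag_len),
                                   background_prob = 0, seed = seed)
  track <- fragment_coverage(frags, genome$length, circular = FALSE)
  list(width = peak_width(track, site_start, background = 0),
       track = track, site_start = site_start)
}

# shared ChIP helper: simulate a library from an occupancy profile and return
# the fold-enrichment track over a matched uniform input
chip_fold_enrichment <- function(occ, n, seed, genome_length) {
  chip <- simulate_chip_fragments(occ, n, seed = seed)
  input <- simulate_input_fragments(genome_length, n, seed = seed + 1L)
  fold_enrichment(normalize_rpbpm(fragment_coverage(chip, genome_length)),
                  normalize_rpbpm(fragment_coverage(input, genome_length)))
}

#' Spreading extent around one isolated site
#'
#' Emulates ChIP of the partition protein bound to a single chromosomal site
#' in a heterologous host: occupancy 1.0 over the site decaying linearly to a
#' 0.02 background over `spreading` bp per side (default 992, i.e. a 2-kb
#' occupied span), 100,000 ChIP fragments (mean 150 bp) plus a matched input,
#' regions called at fold-enrichment >= 2 on a 201-bp-smoothed track.
#'
#' The 0.02 background models a high-specificity immunoprecipitation; extent
#' recovery through a fixed 2-fold cutoff degrades as nonspecific background
#' grows (the crossing moves into the flank), so this study is run in the
#' low-background regime.
#'
#' @param seed integer seed.
#' @param spreading per-side spreading in bp.
#' @param n ChIP library size.
#' @return A list: `extent` (bp), `expected_span` (bp), `regions`.
#' @export
study_single_site_extent <- function(seed = 1L, spreading = 992, n = 1e5) {
  L <- 1e6
  site_start <- 500000
  site <- planted_sites(site_start,
                        make_palindromic_site("GTGAAA", "ACGT"), kd = 30)
  occ <- simulate_occupancy(L, site, spreading = spreading, amplitudes = 1,
                            background = 0.02)
  fe <- chip_fold_enrichment(occ, n, seed, L)
  regions <- call_enriched_regions(fe, threshold = 2, min_run = 200,
                                   merge_gap = 500, smooth = 201)
  list(extent = spreading_extent(regions, site_start + 8, L),
       expected_span = site$width + 2 * spreading, regions = regions)
}

#' Contiguous enrichment extent over the native five-site cluster
#'
#' The five strong sites of the default toy genome (clustered within 5 kb,
#' ~8 kb from the origin) with per-side spreading 2,508 bp give a contiguous
#' occupied span of ~10 kb. 200,000 ChIP fragments plus matched input;
#' regions at fold-enrichment >= 2 on a 201-bp-smoothed track, merge gap
#' 500 bp; extent measured at the cluster centre. Background 0.02 as in [study_single_site_extent()].
#'
#' @param seed integer seed.
#' @param spreading per-side spreading in bp.
#' @param n ChIP library size.
#' @return A list: `extent` (bp), `expected_span` (bp), `regions`,
#'   `cluster_center`.
#' @export
study_cluster_extent <- function(seed = 1L, spreading = 2508, n = 2e5) {
  L <- 1e6
  genome <- toy_genome(101L, with_sequence = FALSE)
  strong <- genome$sites[genome$sites$kd < 1000, ]
  occ <- simulate_occupancy(L, strong, spreading = spreading, amplitudes = 1,
                            background = 0.02)
  fe <- chip_fold_enrichment(occ, n, seed, L)
  regions <- call_enriched_regions(fe, threshold = 2, min_run = 200,
                                   merge_gap = 500, smooth = 201)
  center <- floor((min(strong$start) + max(strong$start + strong$width)) / 2)
  span <- (max(strong$start + strong$width) + spreading) -
    (min(strong$start) - spreading)
  list(extent = spreading_extent(regions, center, L),
       expected_span = span, regions = regions, cluster_center = center)
}

#' Wild-type vs spreading-deficient mutant enrichment ratio
#'
#' Compares mean RPBPM signal over the cluster-containing region between a
#' wild-type simulation (spreading occupancy, amplitude 1.0) and a
#' nucleation-competent but spreading-deficient mutant (nucleation-only
#' occupancy, amplitude 0.2 — the mutant protein is less abundant in vivo),
#' with matched library sizes (100,000 fragments each).
#'
#' Both libraries carry a 0.15 nonspecific background occupancy: in-vivo ChIP
#' libraries are background-dominated (the wild-type in-peak fraction here is
#' ~4%, in the range of real experiments), and it is in that regime that the
#' region-mean signal ratio tracks the underlying occupancy difference rather
#' than the footprint geometry.
#'
#' @param seed integer seed.
#' @param n library size per condition.
#' @param mutant_amplitude relative mutant occupancy.
#' @return A list: `ratio`, `region` (bp, half-open), `wt_track`,
#'   `mutant_track`.
#' @export
study_wt_mutant_ratio <- function(seed = 1L, n = 1e5,
                                  mutant_amplitude = 0.2) {
  L <- 1e6
  genome <- toy_genome(101L, with_sequence = FALSE)
  strong <- genome$sites[genome$sites$kd < 1000, ]
  spreading <- 2508
  occ_wt <- simulate_occupancy(L, strong, spreading = spreading,
                               amplitudes = 1, background = 0.15)
  occ_mut <- simulate_occupancy(L, strong, spreading = 0,
                                amplitudes = mutant_amplitude,
                                background = 0.15)
  wt <- normalize_rpbpm(fragment_coverage(
    simulate_chip_fragments(occ_wt, n, seed = seed), L))
  mut <- normalize_rpbpm(fragment_coverage(
    simulate_chip_fragments(occ_mut, n, seed = seed + 1L), L))
  region <- c(min(strong$start) - spreading,
              max(strong$start + strong$width) + spreading)
  list(ratio = enrichment_ratio(wt, mut, region), region = region,
       wt_track = wt, mutant_track = mut)
}

#' Permissive-zone recovery from comparative insertion libraries
#'
#' On the chromosome-scale 4.04-Mb circular genome, the parS-carrying
#' transposon library is drawn from a fitness landscape with a 10x plateau of
#' `zone_width` bp centred on the native cluster (+4,030 kb, so the zone wraps
#' the origin) and the empty-transposon library from a uniform landscape;
#' 200,000 insertions each, 10-kb bins, zones called at log10 ratio >= 0.
#'
#' @param seed integer seed.
#' @param zone_width plateau full width in bp.
#' @param n insertions per library.
#' @param bin bin width in bp.
#' @return A list: `zone_width` (widest permissive zone, bp), `zones`,
#'   `track`.
#' @export
study_permissive_zone <- function(seed = 1L, zone_width = 5e5, n = 2e5,
                                  bin = 10000) {
  genome <- chromosome_scale_genome()
  center <- 4030000
  landscape <- fitness_landscape(genome$length, zone_center = center,
                                 zone_width = zone_width, plateau = 10,
                                 baseline = 1)
  plus <- simulate_tn_library(landscape, n, seed = seed, label = "parS_plus")
  minus <- simulate_tn_library(rep(1, genome$length), n, seed = seed + 1L,
                               label = "parS_minus")
  track <- log10_ratio_track(bin_insertions(plus, bin),
                             bin_insertions(minus, bin))
  zones <- call_zones(track, permissive_threshold = 0, min_bins = 3,
                      merge_gap_bins = 1)
  perm <- zones[zones$kind == "permissive", ]
  list(zone_width = if (nrow(perm)) max(perm$width) else 0,
       zones = zones, track = track)
}

#' Noise-free dissociation-constant recovery
#'
#' Generates an exact 1:1 isotherm at the standard nine concentrations and
#' refits it; parameter recovery should be limited only by optimiser
#' tolerance.
#'
#' @param kd true dissociation constant in nM.
#' @param rmax maximal response in RU.
#' @return A `kd_fit`.
#' @export
study_kd_recovery <- function(kd, rmax = 100) {
  fit_kd(simulate_spr_titration(kd, rmax, noise_sd = 0))
}
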