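# Shared fixtures, built in code at test time.

# one planted palindromic site on a small linear genome
tiny_site_genome <- function(genome_length = 10000, site_start = 5000,
                             kd = 30, seed = 5L, circular = FALSE) {
  build_genome(genome_length,
               planted_sites(site_start,
                             make_palindromic_site("GTGAAA", "ACGT"),
                             kd = kd),
               seed = seed, circular = circular)
}

# enumerate every fragment with length in len_range fully containing
# [site_start, site_start + width) on a linear genome
enumerate_containing_fragments <- function(genome_length, site_start,
                                           width = 16,
                                           len_range = c(50, 200)) {
  grid <- expand.grid(length = len_range[1]:len_range[2],
                      start = 0:(genome_length - 1))
  keep <- grid$start <= site_start &
    grid$start + grid$length >= site_start + width
  data.frame(start = grid$start[keep], length = grid$length[keep],
             source = "idap")
}

# Independent brute-force oracle for strand-specific summit pairing on a
# linear genome: plain loops over fragments, plain rightmost-max /
# leftmost-max tie-breaks. Deliberately shares no code with the package.
oracle_site_call <- function(fragments, genome_length) {
  upper <- integer(genome_length)
  lower <- integer(genome_length)
  for (i in seq_len(nrow(fragments))) {
    s <- fragments$start[i]
    e <- s + fragments$length[i] - 1
    upper[s + 1] <- upper[s + 1] + 1L
    lower[e + 1] <- lower[e + 1] + 1L
  }
  u <- max(which(upper == max(upper))) - 1  # rightmost max
  l <- min(which(lower == max(lower))) - 1  # leftmost max
  c(site_start = u, site_end = l, length = l - u + 1)
}

# independent per-base occupancy for a single site by direct enumeration
oracle_single_site_occupancy <- function(genome_length, site_start, width,
                                         spreading, amplitude, background) {
  occ <- rep(background, genome_length)
  for (p in 0:(genome_length - 1)) {
    if (p >= site_start && p < site_start + width) {
      occ[p + 1] <- amplitude
    } else {
      d <- if (p < site_start) site_start - p else p - (site_start + width - 1)
      if (d <= spreading)
        occ[p + 1] <- amplitude - (amplitude - background) * d / (spreading + 1)
    }
  }
  occ
}
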