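#' Simulate a nucleation-plus-spreading occupancy profile
#'
#' Models the partition protein's chromosomal footprint: full relative
#' occupancy (`amplitude`) across each planted site (nucleation), a linear
#' decay to `background` over `spreading` bp on each flank (spreading), and
#' `background` elsewhere. Overlapping site contributions combine by maximum.
#' At flank offset `j` (1..spreading) the occupancy is
#' `amplitude - (amplitude - background) * j / (spreading + 1)`, so the
#' strictly-above-background support of an isolated site is exactly
#' `width + 2 * spreading` bp.
#'
#' @param genome a `parb_genome`, or a plain genome length in bp.
#' @param sites site table; defaults to the genome's planted sites.
#' @param spreading per-side spreading extent in bp (0 = nucleation only).
#' @param amplitudes per-site relative occupancy in (0, 1]; recycled to the
#'   number of sites.
#' @param background background occupancy in [0, 1); must be below the
#'   smallest amplitude.
#' @param circular wraps flanks around the origin when TRUE; defaults to the
#'   genome's topology.
#' @return A numeric vector of per-base occupancy in [0, 1] with class
#'   `occupancy_profile`.
#' @export
simulate_occupancy <- function(genome, sites = NULL, spreading = 2000,
                               amplitudes = 1, background = 0,
                               circular = NULL) {
  if (inherits(genome, "parb_genome")) {
    L <- genome$length
    if (is.null(sites)) sites <- genome$sites
    if (is.null(circular)) circular <- genome$circular
  } else {
    L <- as.numeric(genome)
    if (is.null(circular)) circular <- TRUE
    if (is.null(sites)) stop("sites must be supplied with a bare genome length")
  }
  n_sites <- nrow(sites)
  amplitudes <- rep_len(amplitudes, n_sites)
  if (any(amplitudes < 0 | amplitudes > 1))
    stop("amplitudes must lie in [0, 1]")
  if (background < 0 || background >= 1)
    stop("background must lie in [0, 1)")
  if (n_sites > 0 && background >= min(amplitudes))
    stop("background must be below the smallest site amplitude")
  if (spreading < 0) stop("spreading must be >= 0")

  values <- rep(background, L)
  for (i in seq_len(n_sites)) {
    a <- amplitudes[i]
    st <- sites$start[i]
    w <- sites$width[i]
    core <- st:(st + w - 1)
    contrib_pos <- core
    contrib_val <- rep(a, w)
    if (spreading > 0) {
      j <- seq_len(spreading)
      decay <- a - (a - background) * j / (spreading + 1)
      contrib_pos <- c(st - rev(j), contrib_pos, st + w - 1 + j)
      contrib_val <- c(rev(decay), contrib_val, decay)
    }
    if (circular) {
      contrib_pos <- wrap_pos(contrib_pos, L)
    } else {
      keep <- contrib_pos >= 0 & contrib_pos < L
      contrib_pos <- contrib_pos[keep]
      contrib_val <- contrib_val[keep]
    }
    idx <- contrib_pos + 1
    values[idx] <- pmax(values[idx], contrib_val)
  }
  structure(values, class = "occupancy_profile",
            background = background, circular = circular)
}

#' Build a positional fitness landscape for insertion libraries
#'
#' Per-base multiplicative insertion-survival weights: a `baseline` level
#' everywhere, an elevated `plateau` over a zone of `zone_width` bp centred on
#' `zone_center` (wrapping a circular genome), and optionally a second
#' elevated level around the replication terminus.
#'
#' @param genome_length genome length in bp.
#' @param zone_center,zone_width centre (bp) and full width (bp) of the
#'   permissive plateau; `zone_width = 0` gives a flat landscape.
#' @param plateau,baseline weights inside/outside the zone (both >= 0).
#' @param ter_center,ter_width,ter_level optional second elevated zone
#'   (terminus-proximal tolerance).
#' @param circular wrap the zone around the origin?
#' @return Numeric weight vector of length `genome_length`.
#' @export
fitness_landscape <- function(genome_length, zone_center = 0, zone_width = 0,
                              plateau = 10, baseline = 1,
                              ter_center = NULL, ter_width = NULL,
                              ter_level = NULL, circular = TRUE) {
  if (plateau < 0 || baseline < 0) stop("landscape weights must be >= 0")
  w <- rep(baseline, genome_length)
  fill_zone <- function(w, center, width, level) {
    if (width <= 0) return(w)
    pos <- seq(floor(center - width / 2), by = 1, length.out = width)
    if (circular) pos <- wrap_pos(pos, genome_length)
    else pos <- pos[pos >= 0 & pos < genome_length]
    w[pos + 1] <- level
    w
  }
  w <- fill_zone(w, zone_center, zone_width, plateau)
  if (!is.null(ter_center) && !is.null(ter_width) && !is.null(ter_level))
    w <- fill_zone(w, ter_center, ter_width, ter_level)
  w
}
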