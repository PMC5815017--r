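#' Call enriched regions on a signal track
#'
#' Maximal runs of bases with signal at or above `threshold`; runs separated
#' by at most `merge_gap` bp are merged, and merged runs shorter than
#' `min_run` bp are discarded. On circular genomes runs may wrap the origin
#' (a wrapped region is reported with `end > genome length`).
#'
#' @param track a [coverage_track()] (typically fold-enrichment or RPBPM).
#' @param threshold calling threshold in the track's units (default 2-fold).
#' @param min_run minimum region width in bp.
#' @param merge_gap maximum below-threshold gap to bridge, in bp.
#' @param smooth odd moving-average window in bp applied to the track before
#'   thresholding (1 = none). Per-base fold-enrichment of modest-depth
#'   libraries is noisy enough that isolated bases cross any fixed threshold;
#'   a window on the order of the fragment length suppresses these without
#'   shifting run boundaries, since the expected signal is locally linear
#'   there.
#' @return A `data.frame` of regions: `start`, `end` (0-based half-open; `end`
#'   may exceed the genome length for a wrapped region), `width`,
#'   `peak_summit`, `max_signal`, `area` (sum of signal over the region).
#' @export
call_enriched_regions <- function(track, threshold = 2, min_run = 200,
                                  merge_gap = 500, smooth = 1) {
  if (threshold <= 0) stop("threshold must be > 0")
  v <- track$values
  L <- length(v)
  if (smooth > 1) {
    if (smooth %% 2 == 0) stop("smooth window must be odd")
    sm <- stats::filter(v, rep(1 / smooth, smooth), sides = 2,
                        circular = track$circular)
    v <- ifelse(is.na(sm), v, as.numeric(sm))
  }
  r <- rle(v >= threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based half-open
  reg <- data.frame(start = starts[r$values], end = ends[r$values])
  empty <- data.frame(start = numeric(0), end = numeric(0), width = numeric(0),
                      peak_summit = numeric(0), max_signal = numeric(0),
                      area = numeric(0))
  if (nrow(reg) == 0) return(empty)
  # wrap-join: a run touching the end joins one touching the start
  wrapped <- FALSE
  if (track$circular && nrow(reg) > 1 &&
      reg$start[1] == 0 && reg$end[nrow(reg)] == L) {
    reg$end[nrow(reg)] <- L + reg$end[1]
    reg <- reg[-1, , drop = FALSE]
    wrapped <- TRUE
  } else if (track$circular && nrow(reg) == 1 &&
             reg$start[1] == 0 && reg$end[1] == L) {
    wrapped <- FALSE  # whole genome above threshold; nothing to join
  }
  # merge across small gaps (on the unwrapped axis; wrap gap handled below)
  if (nrow(reg) > 1) {
    keep <- list(reg[1, ])
    for (i in 2:nrow(reg)) {
      last <- keep[[length(keep)]]
      if (reg$start[i] - last$end <= merge_gap) {
        keep[[length(keep)]]$end <- reg$end[i]
      } else {
        keep[[length(keep) + 1]] <- reg[i, ]
      }
    }
    reg <- do.call(rbind, keep)
  }
  if (track$circular && !wrapped && nrow(reg) > 1) {
    wrap_gap <- (reg$start[1] + L) - reg$end[nrow(reg)]
    if (wrap_gap <= merge_gap) {
      reg$end[nrow(reg)] <- L + reg$end[1]
      reg <- reg[-1, , drop = FALSE]
    }
  }
  reg$width <- reg$end - reg$start
  reg <- reg[reg$width >= min_run, , drop = FALSE]
  if (nrow(reg) == 0) return(empty)
  idx_of <- function(s, e) wrap_pos(s:(e - 1), L) + 1
  stats_m <- t(vapply(seq_len(nrow(reg)), function(i) {
    idx <- idx_of(reg$start[i], reg$end[i])
    c(peak = reg$start[i] + which.max(v[idx]) - 1,
      mx = max(v[idx]), area = sum(v[idx]))
  }, numeric(3)))
  reg$peak_summit <- wrap_pos(stats_m[, "peak"], L)
  reg$max_signal <- stats_m[, "mx"]
  reg$area <- stats_m[, "area"]
  rownames(reg) <- NULL
  reg
}

region_contains <- function(regions, anchor, genome_length) {
  a <- anchor
  (regions$start <= a & a < regions$end) |
    (regions$start <= a + genome_length & a + genome_length < regions$end)
}

#' Spreading extent at an anchor position
#'
#' Total length (bp) of the union of called regions whose interval contains
#' the anchor — the extent of contiguous enrichment around a site or cluster.
#' Absence of any region covering the anchor is signalled as an error of class
#' `parbseq_undefined_extent` (extent undefined, not zero).
#'
#' @param regions region `data.frame` from [call_enriched_regions()].
#' @param anchor 0-based anchor coordinate (a site or cluster centre).
#' @param genome_length genome length in bp (for wrapped regions).
#' @return Extent in bp.
#' @export
spreading_extent <- function(regions, anchor, genome_length) {
  hit <- region_contains(regions, anchor, genome_length)
  if (!any(hit))
    stop(errorCondition(
      sprintf("no enriched region covers anchor %s: extent undefined", anchor),
      class = "parbseq_undefined_extent"))
  sum(regions$width[hit])
}

#' Width of the peak containing a summit
#'
#' The width of the maximal contiguous run of bases with signal strictly above
#' `background` that contains the summit. For a site-specific (nucleation-only)
#' binder and fragments of fixed length L fully containing a site of width w,
#' the containment-coverage support is `2L - w` bp wide.
#'
#' @param track a [coverage_track()].
#' @param summit 0-based position inside the peak.
#' @param background background signal level; the summit must be above it.
#' @return Peak width in bp.
#' @export
peak_width <- function(track, summit, background = 0) {
  v <- track$values
  L <- length(v)
  if (v[summit + 1] <= background)
    stop("track at the summit is not above background")
  above <- v > background
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  i <- which(r$values & starts <= summit & summit < ends)
  w <- r$lengths[i]
  if (track$circular) {  # join run wrapping the origin
    if (starts[i] == 0 && r$values[length(r$values)] && ends[length(ends)] == L)
      w <- w + r$lengths[length(r$lengths)]
    if (ends[i] == L && r$values[1] && starts[1] == 0 && i != 1)
      w <- w + r$lengths[1]
  }
  w
}

#' Left/right spreading asymmetry around a site
#'
#' Ratio of above-background signal area over a `flank`-bp window left of the
#' site to the matching window right of it; 1 for perfectly symmetric
#' spreading. A zero right-side area is signalled as an error of class
#' `parbseq_undefined_asymmetry`.
#'
#' @param track a [coverage_track()].
#' @param site_start,site_end site interval (0-based, half-open).
#' @param flank window width per side in bp (default 5 kb).
#' @param background background signal level.
#' @return Left/right area ratio.
#' @export
peak_asymmetry <- function(track, site_start, site_end, flank = 5000,
                           background = 0) {
  v <- track$values
  L <- length(v)
  grab <- function(pos) {
    if (track$circular) pos <- wrap_pos(pos, L)
    else pos <- pos[pos >= 0 & pos < L]
    v[pos + 1]
  }
  left <- sum(pmax(grab((site_start - flank):(site_start - 1)) - background, 0))
  right <- sum(pmax(grab(site_end:(site_end + flank - 1)) - background, 0))
  if (right == 0)
    stop(errorCondition("right-flank area is zero: asymmetry undefined",
                        class = "parbseq_undefined_asymmetry"))
  left / right
}

#' Mean-signal enrichment ratio between two tracks over a region
#'
#' `(mean of track_a over the region) / (mean of track_b over the region)`,
#' e.g. wild-type vs spreading-deficient mutant ChIP signal over the site
#' cluster. Both tracks must be in the same (normalised) units.
#'
#' @param track_a,track_b equally normalised `coverage_track`s.
#' @param region numeric `c(start, end)`, 0-based half-open (may wrap).
#' @return Fold ratio.
#' @export
enrichment_ratio <- function(track_a, track_b, region) {
  if (!identical(track_a$units, track_b$units))
    stop("tracks are not in the same units")
  if (length(track_a$values) != length(track_b$values))
    stop("tracks have different lengths")
  L <- length(track_a$values)
  if (region[2] <= region[1]) stop("region is empty")
  idx <- wrap_pos(region[1]:(region[2] - 1), L) + 1
  mb <- mean(track_b$values[idx])
  if (mb == 0)
    stop(errorCondition("track_b has zero mean over the region: ratio undefined",
                        class = "parbseq_undefined_ratio"))
  mean(track_a$values[idx]) / mb
}
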