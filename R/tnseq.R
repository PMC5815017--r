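#' Bin insertion counts along the genome
#'
#' Sums per-position insertion read counts into fixed-width bins (default
#' 10 kb) tiling the genome; a final partial bin is kept and flagged.
#'
#' @param library an `insertion_library` from [simulate_tn_library()] or
#'   [read_insertions_bed()].
#' @param bin bin width in bp.
#' @return A list with `bin_starts` (bp), `counts`, `bin`, `genome_length`,
#'   `total`, `partial_last`.
#' @export
bin_insertions <- function(library, bin = 10000) {
  if (bin < 1) stop("bin must be >= 1")
  L <- library$genome_length
  nbins <- ceiling(L / bin)
  idx <- floor(library$positions / bin) + 1
  counts <- numeric(nbins)
  agg <- rowsum(as.numeric(library$counts), idx)
  counts[as.integer(rownames(agg))] <- agg[, 1]
  list(bin_starts = (seq_len(nbins) - 1) * bin, counts = counts, bin = bin,
       genome_length = L, total = library$total_insertions,
       partial_last = (L %% bin) != 0)
}

#' Log10 insertion-frequency ratio track
#'
#' Compares insertion *frequencies* (count / library total) between a
#' parS-carrying and an empty-transposon library per bin:
#' `log10( ((plus + pc) / plus_total) / ((minus + pc) / minus_total) )`.
#' Frequencies (not raw counts) are compared so unequal sequencing depths
#' cancel; the pseudocount `pc` (default 1) avoids log of zero.
#'
#' @param plus_bins,minus_bins binned counts from [bin_insertions()] on the
#'   same bin grid (parS+ is the numerator).
#' @param plus_total,minus_total library sizes; default from the bin objects.
#' @param pseudocount added to each bin count.
#' @return A list of class `ratio_track`: `bin_starts`, `log10_ratio`, `bin`,
#'   `plus_total`, `minus_total`, `genome_length`.
#' @export
log10_ratio_track <- function(plus_bins, minus_bins,
                              plus_total = plus_bins$total,
                              minus_total = minus_bins$total,
                              pseudocount = 1) {
  if (!identical(plus_bins$bin_starts, minus_bins$bin_starts) ||
      plus_bins$bin != minus_bins$bin)
    stop("plus and minus libraries are binned on different grids")
  if (plus_total < 1 || minus_total < 1) stop("library totals must be >= 1")
  lr <- log10(((plus_bins$counts + pseudocount) / plus_total) /
                ((minus_bins$counts + pseudocount) / minus_total))
  structure(
    list(bin_starts = plus_bins$bin_starts, log10_ratio = lr,
         bin = plus_bins$bin, plus_total = plus_total,
         minus_total = minus_total, genome_length = plus_bins$genome_length),
    class = "ratio_track"
  )
}

#' @export
print.ratio_track <- function(x, ...) {
  cat(sprintf("<ratio_track> %d bins of %s bp; log10 ratio in [%.2f, %.2f]\n",
              length(x$log10_ratio), format(x$bin, big.mark = ","),
              min(x$log10_ratio), max(x$log10_ratio)))
  invisible(x)
}

# maximal runs of `flag`, circular merge across the origin, bridging up to
# merge_gap FALSE bins; returns data.frame(first, last) of 1-based bin indices
# (last may exceed nbins for a wrapped run)
bin_runs <- function(flag, merge_gap, min_bins, circular) {
  n <- length(flag)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(first = starts[r$values], last = ends[r$values])
  if (nrow(runs) == 0) return(runs)
  if (circular && nrow(runs) > 1 && runs$first[1] == 1 && runs$last[nrow(runs)] == n) {
    runs$last[nrow(runs)] <- n + runs$last[1]
    runs <- runs[-1, , drop = FALSE]
  }
  if (nrow(runs) > 1) {
    keep <- list(runs[1, ])
    for (i in 2:nrow(runs)) {
      last <- keep[[length(keep)]]
      if (runs$first[i] - last$last - 1 <= merge_gap) {
        keep[[length(keep)]]$last <- runs$last[i]
      } else {
        keep[[length(keep) + 1]] <- runs[i, ]
      }
    }
    runs <- do.call(rbind, keep)
  }
  if (circular && nrow(runs) > 1) {
    wrap_gap <- (runs$first[1] + n) - runs$last[nrow(runs)] - 1
    if (wrap_gap <= merge_gap) {
      runs$last[nrow(runs)] <- n + runs$last[1]
      runs <- runs[-1, , drop = FALSE]
    }
  }
  runs[runs$last - runs$first + 1 >= min_bins, , drop = FALSE]
}

#' Call permissive and disfavoured zones from a ratio track
#'
#' Permissive zones are maximal runs of bins with log10 ratio at or above
#' `permissive_threshold` (the parS-carrying transposon inserted at least as
#' frequently as the empty one); disfavoured zones are runs at or below
#' `-permissive_threshold`. Runs are merged across up to `merge_gap_bins`
#' off-threshold bins and must span at least `min_bins` bins. Circular-aware.
#'
#' @param track a `ratio_track`.
#' @param permissive_threshold log10-ratio threshold (default 0).
#' @param min_bins minimum zone length in bins.
#' @param merge_gap_bins off-threshold gap to bridge, in bins.
#' @return A `data.frame` of zones: `start`, `end` (bp, half-open; `end` may
#'   exceed the genome length for a wrapped zone), `width`, `kind`
#'   (`"permissive"`/`"disfavoured"`), `mean_log10_ratio`.
#' @export
call_zones <- function(track, permissive_threshold = 0, min_bins = 3,
                       merge_gap_bins = 1) {
  if (!is.finite(permissive_threshold)) stop("threshold must be finite")
  lr <- track$log10_ratio
  n <- length(lr)
  circular <- TRUE
  one_kind <- function(flag, kind) {
    runs <- bin_runs(flag, merge_gap_bins, min_bins, circular)
    if (nrow(runs) == 0)
      return(data.frame(start = numeric(0), end = numeric(0),
                        width = numeric(0), kind = character(0),
                        mean_log10_ratio = numeric(0)))
    data.frame(
      start = track$bin_starts[runs$first],
      end = ifelse(runs$last > n,
                   track$genome_length + pmin(track$bin_starts[runs$last - n] +
                                                track$bin, track$genome_length),
                   pmin(track$bin_starts[runs$last] + track$bin,
                        track$genome_length)),
      kind = kind,
      mean_log10_ratio = vapply(seq_len(nrow(runs)), function(i) {
        idx <- ((runs$first[i]:runs$last[i]) - 1) %% n + 1
        mean(lr[idx])
      }, numeric(1))
    ) -> z
    z$width <- z$end - z$start
    z[, c("start", "end", "width", "kind", "mean_log10_ratio")]
  }
  out <- rbind(one_kind(lr >= permissive_threshold, "permissive"),
               one_kind(lr <= -permissive_threshold, "disfavoured"))
  rownames(out) <- NULL
  out
}

#' Call insertion hotspots from a ratio track
#'
#' Bins whose log10 ratio exceeds `median + z_threshold * MAD-based robust sd`
#' of the track; adjacent hotspot bins are merged. A constant track (zero MAD)
#' yields no hotspots and is flagged via the `degenerate_scale` attribute.
#'
#' @param track a `ratio_track`.
#' @param z_threshold robust z-score cutoff (default 4).
#' @return A zone `data.frame` (`kind = "hotspot"`), possibly empty.
#' @export
call_hotspots <- function(track, z_threshold = 4) {
  lr <- track$log10_ratio
  if (length(lr) == 0) stop("empty ratio track")
  med <- stats::median(lr)
  s <- stats::mad(lr)  # 1.4826 * median absolute deviation
  empty <- data.frame(start = numeric(0), end = numeric(0), width = numeric(0),
                      kind = character(0), mean_log10_ratio = numeric(0))
  if (s == 0) {
    attr(empty, "degenerate_scale") <- TRUE
    return(empty)
  }
  flag <- lr > med + z_threshold * s
  runs <- bin_runs(flag, merge_gap = 0, min_bins = 1, circular = TRUE)
  if (nrow(runs) == 0) return(empty)
  n <- length(lr)
  out <- data.frame(
    start = track$bin_starts[runs$first],
    end = ifelse(runs$last > n,
                 track$genome_length + pmin(track$bin_starts[runs$last - n] +
                                              track$bin, track$genome_length),
                 pmin(track$bin_starts[runs$last] + track$bin,
                      track$genome_length)),
    kind = "hotspot",
    mean_log10_ratio = vapply(seq_len(nrow(runs)), function(i) {
      idx <- ((runs$first[i]:runs$last[i]) - 1) %% n + 1
      mean(lr[idx])
    }, numeric(1))
  )
  out$width <- out$end - out$start
  rownames(out) <- NULL
  out[, c("start", "end", "width", "kind", "mean_log10_ratio")]
}

#' Remap a coordinate across a chromosomal inversion
#'
#' Positions inside the inverted segment `[left, right)` reflect to
#' `left + right - 1 - position`; positions outside are unchanged. The map is
#' an involution (applying it twice is the identity) and preserves adjacency
#' inside the segment. Used to compare insertion profiles between strains
#' carrying large engineered inversions (Flip strains) and the reference
#' orientation.
#'
#' @param position coordinate(s), 0-based.
#' @param left,right inversion endpoints in bp (0-based half-open,
#'   `left < right`).
#' @return Remapped coordinate(s).
#' @export
remap_inversion <- function(position, left, right) {
  if (left >= right) stop("inversion needs left < right")
  inside <- position >= left & position < right
  out <- position
  out[inside] <- left + right - 1 - position[inside]
  out
}
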