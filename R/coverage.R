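#' Coverage tracks
#'
#' A coverage track is a per-base (or per-bin) nonnegative signal over the
#' genome together with a units tag (`"raw"`, `"RPBPM"`, `"RPKPM"`,
#' `"fold_enrichment"`) and the library size used for normalisation.
#'
#' @param values numeric signal vector.
#' @param units units tag.
#' @param total_mapped library size used for normalisation (NA for raw).
#' @param genome_length genome length in bp.
#' @param circular circular genome?
#' @param bin bin width in bp (NA for per-base tracks).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, units = "raw", total_mapped = NA,
                           genome_length = length(values), circular = TRUE,
                           bin = NA) {
  if (any(values < 0)) stop("coverage values must be >= 0")
  structure(
    list(values = as.numeric(values), units = units,
         total_mapped = total_mapped, genome_length = genome_length,
         circular = circular, bin = bin),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s values [%s]%s; max %.4g, mean %.4g\n",
              format(length(x$values), big.mark = ","), x$units,
              if (!is.na(x$bin)) sprintf(" in %d-bp bins", x$bin) else "",
              max(x$values), mean(x$values)))
  invisible(x)
}

check_fragments <- function(fragments, genome_length, circular) {
  if (any(fragments$length < 1)) stop("fragment lengths must be >= 1")
  if (any(fragments$start < 0 | fragments$start >= genome_length))
    stop("fragment starts must lie in [0, genome length)")
  if (!circular) {
    bad <- fragments$start + fragments$length > genome_length
    if (any(bad))
      stop("fragment(s) at row(s) ", paste(head(which(bad), 5), collapse = ", "),
           " extend past the end of a linear genome")
  }
  invisible(TRUE)
}

# add +1 over [start, end) (0-based half-open, already within [0, L]) using a
# difference array
add_segments <- function(delta, start, end) {
  inc <- tabulate(start + 1L, nbins = length(delta))
  dec <- tabulate(end + 1L, nbins = length(delta))
  delta + inc - dec
}

#' Per-base fragment coverage
#'
#' `values[i]` is the number of fragments whose interval covers base `i`.
#' The sum of the track equals the sum of fragment lengths (coverage
#' conservation). Fragments may wrap the origin of a circular genome.
#'
#' @param fragments fragment `data.frame` (`start` 0-based, `length`).
#' @param genome_length genome length in bp.
#' @param circular circular genome?
#' @return A raw [coverage_track()].
#' @export
fragment_coverage <- function(fragments, genome_length,
                              circular = TRUE) {
  L <- as.integer(genome_length)
  check_fragments(fragments, L, circular)
  delta <- numeric(L + 1L)
  if (nrow(fragments) > 0) {
    s <- as.integer(fragments$start)
    e <- s + as.integer(fragments$length)
    e1 <- pmin(e, L)
    delta <- add_segments(delta, s, e1)
    wrapped <- e > L
    if (any(wrapped)) {
      delta <- add_segments(delta, rep(0L, sum(wrapped)), e[wrapped] - L)
    }
  }
  values <- cumsum(delta)[seq_len(L)]
  coverage_track(values, units = "raw", total_mapped = nrow(fragments),
                 genome_length = L, circular = circular)
}

#' Depth-normalise a raw track to reads per base pair per million mapped
#'
#' RPBPM: `raw / (total_mapped / 1e6)`.
#'
#' @param track a raw [coverage_track()].
#' @param total_mapped total mapped fragments in the library; defaults to the
#'   track's recorded library size.
#' @return A `coverage_track` in RPBPM units.
#' @export
normalize_rpbpm <- function(track, total_mapped = track$total_mapped) {
  if (is.na(total_mapped) || total_mapped < 1)
    stop("total_mapped must be >= 1")
  coverage_track(track$values / (total_mapped / 1e6), units = "RPBPM",
                 total_mapped = total_mapped,
                 genome_length = track$genome_length,
                 circular = track$circular, bin = track$bin)
}

#' Bin and depth-normalise a raw track (reads per kb per million mapped)
#'
#' Per-bin value: `(sum of raw values in the bin) / (total_mapped / 1e6)`.
#' A final partial bin is kept and flagged via the `partial_last` attribute.
#'
#' @param track a raw per-base [coverage_track()].
#' @param total_mapped library size for normalisation.
#' @param bin bin width in bp (default 1000 = per-kb).
#' @return A binned `coverage_track` in RPKPM units.
#' @export
bin_rpkpm <- function(track, total_mapped = track$total_mapped, bin = 1000) {
  if (bin < 1) stop("bin must be >= 1")
  if (is.na(total_mapped) || total_mapped < 1)
    stop("total_mapped must be >= 1")
  L <- track$genome_length
  nbins <- ceiling(L / bin)
  cs <- cumsum(track$values)
  ends <- pmin(seq_len(nbins) * bin, L)
  sums <- cs[ends] - c(0, cs[ends[-nbins]])
  out <- coverage_track(sums / (total_mapped / 1e6), units = "RPKPM",
                        total_mapped = total_mapped, genome_length = L,
                        circular = track$circular, bin = bin)
  attr(out, "partial_last") <- (L %% bin) != 0
  out
}

#' Strand-specific fragment 5'-end counts
#'
#' Each double-stranded fragment contributes one 5' end to each strand: the
#' upper-strand 5' end at its leftmost base and the lower-strand 5' end at its
#' rightmost base. The paired per-base count arrays are the input to
#' nucleotide-resolution site calling.
#'
#' @inheritParams fragment_coverage
#' @return A list of class `strand_ends` with integer vectors `upper` and
#'   `lower` (length `genome_length`), `n_fragments`, `genome_length`,
#'   `circular`.
#' @export
strand_end_counts <- function(fragments, genome_length, circular = TRUE) {
  L <- as.integer(genome_length)
  check_fragments(fragments, L, circular)
  s <- as.integer(fragments$start)
  e <- as.integer(wrap_pos(fragments$start + fragments$length - 1, L))
  structure(
    list(upper = tabulate(s + 1L, nbins = L),
         lower = tabulate(e + 1L, nbins = L),
         n_fragments = nrow(fragments),
         genome_length = L, circular = circular),
    class = "strand_ends"
  )
}

#' @export
print.strand_ends <- function(x, ...) {
  cat(sprintf("<strand_ends> %s fragments on %s bp; max upper %d, max lower %d\n",
              format(x$n_fragments, big.mark = ","),
              format(x$genome_length, big.mark = ","),
              max(x$upper), max(x$lower)))
  invisible(x)
}

#' Fold enrichment of a ChIP track over a control track
#'
#' `(chip + pseudocount) / (control + pseudocount)` per base. The pseudocount
#' (default 0.1 RPBPM) stabilises bases with no control signal.
#'
#' @param chip,control equally normalised `coverage_track`s of equal length.
#' @param pseudocount positive stabiliser, in the tracks' units.
#' @return A `coverage_track` in `fold_enrichment` units.
#' @export
fold_enrichment <- function(chip, control, pseudocount = 0.1) {
  if (length(chip$values) != length(control$values))
    stop("chip and control tracks have different lengths")
  if (!identical(chip$units, control$units))
    stop("chip and control tracks are not in the same units")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  coverage_track((chip$values + pseudocount) / (control$values + pseudocount),
                 units = "fold_enrichment", total_mapped = chip$total_mapped,
                 genome_length = chip$genome_length,
                 circular = chip$circular, bin = chip$bin)
}

#' Fragment size statistics
#'
#' Mean, median and a histogram of fragment lengths (the size distribution of
#' the sequenced material).
#'
#' @param fragments nonempty fragment `data.frame`.
#' @param bin_width histogram bin width in bp.
#' @return A list with `mean`, `median`, `n` and a `histogram` data frame
#'   (`length_bin_start`, `count`).
#' @export
fragment_size_stats <- function(fragments, bin_width = 10) {
  if (nrow(fragments) == 0) stop("fragment list is empty")
  len <- fragments$length
  brk <- floor(len / bin_width) * bin_width
  tab <- table(brk)
  list(mean = mean(len), median = stats::median(len), n = length(len),
       histogram = data.frame(length_bin_start = as.numeric(names(tab)),
                              count = as.integer(tab)))
}
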