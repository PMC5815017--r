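#' Find summits in a per-base 5'-end count array
#'
#' Summits are selected greedily in decreasing count order; once a summit is
#' accepted, further candidates within `min_separation` bp are suppressed.
#'
#' Because every fragment that fully contains a site has its upper-strand 5'
#' end at or left of the site's first base, the expected upper-strand count
#' profile plateaus against a cliff at the site edge (and symmetrically for
#' the lower strand). The summit of a peak is therefore taken as the
#' *directional edge of its plateau*: the rightmost (upper strand) or leftmost
#' (lower strand) position within the peak's support run whose count is at
#' least `plateau_frac` of the peak count. On noise-free profiles this is
#' exactly the rightmost-max / leftmost-max tie-break; on sampled data it
#' tolerates multinomial noise on the flat top. The support run around a peak
#' extends over positive counts, bridging up to `gap_tol` consecutive zero
#' positions.
#'
#' @param counts per-base nonnegative count vector.
#' @param min_height minimum count for a position to seed a summit (> 0).
#' @param min_separation suppression radius in bp between summits.
#' @param tie_break `"rightmost"` for upper-strand profiles, `"leftmost"` for
#'   lower-strand profiles.
#' @param plateau_frac fraction of the peak count that still belongs to the
#'   plateau.
#' @param gap_tol zero-gap length (bp) that does not break a peak's support
#'   run.
#' @param circular treat the count vector as circular?
#' @return A `data.frame` with `position` (0-based) and `height`, sorted by
#'   position. Zero rows when nothing reaches `min_height`.
#' @export
find_summits <- function(counts, min_height, min_separation = 200,
                         tie_break = c("rightmost", "leftmost"),
                         plateau_frac = 0.25, gap_tol = 5,
                         circular = FALSE) {
  tie_break <- match.arg(tie_break)
  if (min_height <= 0) stop("min_height must be > 0")
  counts <- as.numeric(counts)
  L <- length(counts)
  live <- counts >= min_height
  out_pos <- numeric(0)
  out_h <- numeric(0)

  at <- function(i) counts[wrap_pos(i, L) + 1]  # 0-based accessor

  # expand a support run from p0 (0-based) in one direction, bridging up to
  # gap_tol non-positive positions; returns last in-run position
  expand <- function(p0, step) {
    p <- p0
    gap <- 0
    limit <- L - 1
    for (k in seq_len(limit)) {
      q <- p0 + step * k
      if (!circular && (q < 0 || q >= L)) break
      if (at(q) > 0) {
        p <- q
        gap <- 0
      } else {
        gap <- gap + 1
        if (gap > gap_tol) break
      }
    }
    p
  }

  while (any(live)) {
    h <- max(counts[live])
    cand <- which(live & counts == h) - 1  # 0-based
    p0 <- if (tie_break == "rightmost") max(cand) else min(cand)
    left <- expand(p0, -1L)
    right <- expand(p0, +1L)
    run <- left:right  # may exceed [0, L) on circular genomes
    ok <- at(run) >= plateau_frac * h
    summit <- if (tie_break == "rightmost") max(run[ok]) else min(run[ok])
    s_height <- at(summit)
    summit <- wrap_pos(summit, L)
    out_pos <- c(out_pos, summit)
    out_h <- c(out_h, s_height)
    # suppress the whole run plus min_separation around the summit
    kill <- c(run, (summit - min_separation):(summit + min_separation))
    kill <- unique(wrap_pos(kill, L)) + 1
    kill <- kill[kill >= 1 & kill <= L]
    live[kill] <- FALSE
  }
  out <- data.frame(position = out_pos, height = out_h)
  out[order(out$position), , drop = FALSE]
}

# circular-aware gap from upper summit u to lower summit l: inclusive
# interval length (l - u + 1)
summit_gap <- function(u, l, genome_length, circular) {
  g <- l - u + 1
  if (circular) {
    neg <- !is.na(g) & g < 1
    g[neg] <- g[neg] + genome_length
  }
  g
}

#' Pair upper- and lower-strand summits into binding-site calls
#'
#' The minimal binding sequence is delimited by the summit of the upper-strand
#' 5'-end profile and that of the lower-strand profile: each upper summit `u`
#' is paired with the nearest unused lower summit `l` such that the inclusive
#' interval length `l - u + 1` lies in `[min_gap, max_gap]` (circular-aware).
#' Pairing proceeds in decreasing order of summit height; each summit is used
#' at most once. Unpaired summits are reported via the `"unpaired"` attribute,
#' never silently dropped.
#'
#' @param upper_summits,lower_summits summit `data.frame`s from
#'   [find_summits()] (sorted by position).
#' @param min_gap,max_gap allowed inclusive call length in bp; the defaults
#'   (8, 40) bracket a 16-bp site against end-count jitter.
#' @param genome_length genome length in bp (needed for circular pairing).
#' @param circular circular genome?
#' @return A `data.frame` of calls: `site_start`, `site_end` (both inclusive,
#'   0-based), `length`, `upper_summit`, `lower_summit`, `height`
#'   (min of the two summit counts), sorted by height descending; attribute
#'   `unpaired` holds the leftover summits.
#' @export
pair_summits <- function(upper_summits, lower_summits, min_gap = 8,
                         max_gap = 40, genome_length = NULL,
                         circular = FALSE) {
  if (circular && is.null(genome_length))
    stop("genome_length is required for circular pairing")
  nu <- nrow(upper_summits)
  nl <- nrow(lower_summits)
  used_l <- rep(FALSE, nl)
  paired_u <- rep(FALSE, nu)
  calls <- list()
  for (i in order(-upper_summits$height)) {
    u <- upper_summits$position[i]
    if (nl == 0) break
    g <- summit_gap(u, lower_summits$position,
                    genome_length %||% Inf, circular)
    ok <- !used_l & g >= min_gap & g <= max_gap
    if (!any(ok)) next
    j <- which(ok)[which.min(g[ok])]
    used_l[j] <- TRUE
    paired_u[i] <- TRUE
    calls[[length(calls) + 1]] <- data.frame(
      site_start = u,
      site_end = lower_summits$position[j],
      length = g[j],
      upper_summit = u,
      lower_summit = lower_summits$position[j],
      height = min(upper_summits$height[i], lower_summits$height[j])
    )
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(site_start = numeric(0), site_end = numeric(0),
               length = numeric(0), upper_summit = numeric(0),
               lower_summit = numeric(0), height = numeric(0))
  out <- out[order(-out$height), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unpaired") <- list(
    upper = upper_summits[!paired_u, , drop = FALSE],
    lower = lower_summits[!used_l, , drop = FALSE]
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# default detection threshold: 5x the genome-wide median positive end count;
# a fully subtracted (all-zero) signal gets an infinite threshold -> no calls
default_min_height <- function(upper, lower) {
  pos <- c(upper[upper > 0], lower[lower > 0])
  if (length(pos) == 0) return(Inf)
  5 * stats::median(pos)
}

#' Call binding sites at nucleotide resolution from affinity-purification
#' fragments
#'
#' The full strand-specific pipeline: per-base 5'-end counts for the sample
#' (and, when given, a bead-only control, which is depth-scaled and
#' subtracted, floored at zero), summit detection on each strand with
#' edge-directed tie-breaks, summit pairing, and sequence/palindrome
#' annotation from the genome sequence.
#'
#' @param idap_fragments sample fragment `data.frame`.
#' @param control_fragments optional control fragment `data.frame`
#'   (no-protein beads); `NULL` disables subtraction.
#' @param genome a `parb_genome`.
#' @param min_height summit detection threshold; default 5x the genome-wide
#'   median positive end count (after control subtraction).
#' @param min_gap,max_gap allowed call length bounds in bp.
#' @param min_separation summit suppression radius in bp.
#' @param plateau_frac plateau membership fraction (see [find_summits()]).
#' @return A call `data.frame` as from [pair_summits()], sorted by height
#'   descending, with `sequence` and `palindrome_score` columns when the
#'   genome carries a sequence.
#' @export
call_sites <- function(idap_fragments, control_fragments = NULL, genome,
                       min_height = NULL, min_gap = 8, max_gap = 40,
                       min_separation = 200, plateau_frac = 0.25) {
  if (is.null(idap_fragments) || nrow(idap_fragments) == 0)
    stop("sample fragment set is empty")
  L <- genome$length
  ends <- strand_end_counts(idap_fragments, L, genome$circular)
  upper <- as.numeric(ends$upper)
  lower <- as.numeric(ends$lower)
  if (!is.null(control_fragments) && nrow(control_fragments) > 0) {
    ctrl <- strand_end_counts(control_fragments, L, genome$circular)
    scale <- nrow(idap_fragments) / nrow(control_fragments)
    upper <- pmax(upper - scale * ctrl$upper, 0)
    lower <- pmax(lower - scale * ctrl$lower, 0)
  }
  if (is.null(min_height)) min_height <- default_min_height(upper, lower)
  us <- find_summits(upper, min_height, min_separation, "rightmost",
                     plateau_frac, circular = genome$circular)
  ls <- find_summits(lower, min_height, min_separation, "leftmost",
                     plateau_frac, circular = genome$circular)
  calls <- pair_summits(us, ls, min_gap, max_gap, L, genome$circular)
  if (!is.null(genome$sequence) && nrow(calls) > 0) {
    calls$sequence <- vapply(
      seq_len(nrow(calls)),
      function(i) genome_subseq(genome, calls$site_start[i], calls$site_end[i]),
      character(1)
    )
    calls$palindrome_score <- vapply(calls$sequence, palindrome_score,
                                     numeric(1), USE.NAMES = FALSE)
  }
  attr(calls, "min_height") <- min_height
  calls
}

#' Palindromicity score of a nucleotide sequence
#'
#' The number of positions `i` at which the base equals the complement of the
#' base at the mirrored position `n - 1 - i`. A perfect palindrome of length
#' `n` scores `n`.
#'
#' @param sequence nonempty string over A/C/G/T.
#' @return Integer score in `0..nchar(sequence)`.
#' @examples
#' palindrome_score("GAATTC")  # 6
#' @export
palindrome_score <- function(sequence) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence) || !grepl("^[ACGT]+$", sequence))
    stop("sequence must be a nonempty string over {A,C,G,T}")
  s <- strsplit(sequence, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  sum(s == comp[rev(s)])
}
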