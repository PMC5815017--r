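#' @keywords internal
"_PACKAGE"

# Coordinates are 0-based, half-open everywhere internally. Circular genomes
# wrap modulo length; helper kept internal.
wrap_pos <- function(pos, genome_length) {
  pos %% genome_length
}

#' Construct a planted binding-site table
#'
#' A planted site is a short (by default 16-bp) sequence placed on a toy
#' genome together with the equilibrium dissociation constant that governs how
#' strongly the partition protein binds it in simulated affinity-purification
#' experiments.
#'
#' @param start 0-based start coordinate(s), one per site.
#' @param sequence site sequence(s) over A/C/G/T; recycled lengths must match.
#' @param kd dissociation constant(s) in nM; must be positive.
#' @param label free-text site label(s).
#' @return A `data.frame` with columns `start`, `width`, `sequence`, `kd`,
#'   `label`.
#' @export
planted_sites <- function(start, sequence, kd, label = NULL) {
  sequence <- toupper(sequence)
  if (any(!grepl("^[ACGT]+$", sequence)))
    stop("site sequences must be over {A,C,G,T}")
  if (any(kd <= 0)) stop("site kd must be > 0 (nM)")
  n <- max(length(start), length(sequence), length(kd))
  if (is.null(label))
    label <- if (n == 0) character(0) else paste0("site", seq_len(n))
  out <- data.frame(
    start = as.numeric(start),
    width = nchar(sequence),
    sequence = sequence,
    kd = as.numeric(kd),
    label = label,
    stringsAsFactors = FALSE
  )
  out[order(out$start), , drop = FALSE]
}

#' Assemble a palindromic 16-bp site from a conserved half-site
#'
#' parS-family sites are palindromes. The assembled site is
#' `reverse-complement(half_site) + spacer + half_site`, so its outer 6-mers
#' are exact reverse complements and the conserved half-site (GTGAAA in
#' Caulobacter) forms the 3' half.
#'
#' @param half_site 6-mer over A/C/G/T.
#' @param spacer 4-mer over A/C/G/T separating the two half-sites.
#' @return A 16-character site sequence.
#' @examples
#' make_palindromic_site("GTGAAA", "ACGT")
#' @export
make_palindromic_site <- function(half_site, spacer) {
  half_site <- toupper(half_site)
  spacer <- toupper(spacer)
  if (nchar(half_site) != 6L || !grepl("^[ACGT]{6}$", half_site))
    stop("half_site must be a 6-mer over {A,C,G,T}")
  if (nchar(spacer) != 4L || !grepl("^[ACGT]{4}$", spacer))
    stop("spacer must be a 4-mer over {A,C,G,T}")
  paste0(revcomp(half_site), spacer, half_site)
}

# Reverse complement of a plain character string (thin wrapper over
# Biostrings so ambiguity codes and validation stay with the standard tool).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Default set of seven planted parS-like sites
#'
#' Seven synthetic palindromic 16-mers built around the conserved GTGAAA
#' half-site: five strong sites (Kd in the tens of nM) clustered within a 5-kb
#' window, flanked by two weak sites (Kd >= 1 uM), mirroring the strong/weak
#' split of the natively clustered sites. The sequences are synthetic
#' placeholders, not the published site sequences.
#'
#' @return A site table as returned by [planted_sites()].
#' @export
default_parS_sites <- function() {
  spacers <- c("ATGC", "ACGT", "ATAT", "GCGC", "TGCA", "GATC", "AATT")
  seqs <- vapply(spacers, make_palindromic_site, character(1),
                 half_site = "GTGAAA")
  planted_sites(
    start = c(4200, 5500, 6600, 7700, 8800, 9900, 10450),
    sequence = unname(seqs),
    kd = c(1500, 30, 28, 32, 35, 2500, 45),
    label = paste0("parS", 1:7)
  )
}

#' Build a toy genome with planted sites
#'
#' Generates a random nucleotide sequence of the requested length and plants
#' each site's sequence at its start coordinate. Deterministic for a fixed
#' seed.
#'
#' @param length genome length in bp.
#' @param sites site table from [planted_sites()]; may have zero rows.
#' @param seed integer seed driving the random background sequence.
#' @param circular is the genome circular? Site intervals may wrap the origin
#'   of a circular genome.
#' @param origin 0-based coordinate of the replication origin (annotation
#'   only).
#' @param with_sequence set `FALSE` to skip sequence generation (coordinates
#'   and site table only); useful for chromosome-scale insertion simulations.
#' @return An object of class `parb_genome`: a list with `length`, `circular`,
#'   `origin`, `sites` and `sequence` (a single character string, or `NULL`).
#' @export
build_genome <- function(length, sites = planted_sites(numeric(0), character(0), numeric(0))[0, ],
                         seed = 1L, circular = TRUE, origin = 0,
                         with_sequence = TRUE) {
  length <- as.numeric(length)
  if (length < 1) stop("genome length must be >= 1")
  if (nrow(sites) > 0) {
    ends <- sites$start + sites$width
    if (!circular && any(ends > length))
      stop("site(s) ", paste(sites$label[ends > length], collapse = ", "),
           " extend past the end of a linear genome")
    if (any(sites$start < 0) || any(sites$start >= length))
      stop("site starts must lie in [0, genome length)")
    # overlap check on the circle: compare consecutive sites in start order,
    # plus the wrap pair
    if (nrow(sites) > 1) {
      s <- sites[order(sites$start), ]
      gap <- c(s$start[-1] - (s$start[-nrow(s)] + s$width[-nrow(s)]),
               if (circular)
                 s$start[1] + length - (s$start[nrow(s)] + s$width[nrow(s)])
               else 1)
      if (any(gap < 0)) {
        i <- which(gap < 0)[1]
        j <- if (i == nrow(s)) 1 else i + 1
        stop("planted sites overlap: ", s$label[i], " and ", s$label[j])
      }
    }
  }
  sequence <- NULL
  if (with_sequence) {
    sequence <- withr::with_seed(seed, {
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = "")
    })
    if (nrow(sites) > 0) {
      for (i in seq_len(nrow(sites))) {
        st <- sites$start[i]
        w <- sites$width[i]
        if (st + w <= length) {
          substr(sequence, st + 1, st + w) <- sites$sequence[i]
        } else {
          head_w <- length - st
          substr(sequence, st + 1, length) <-
            substr(sites$sequence[i], 1, head_w)
          substr(sequence, 1, w - head_w) <-
            substr(sites$sequence[i], head_w + 1, w)
        }
      }
    }
  }
  structure(
    list(length = length, circular = circular, origin = origin,
         sites = sites, sequence = sequence),
    class = "parb_genome"
  )
}

#' @export
print.parb_genome <- function(x, ...) {
  cat(sprintf("<parb_genome> %s bp, %s, %d planted site(s)%s\n",
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear",
              nrow(x$sites),
              if (is.null(x$sequence)) " (no sequence)" else ""))
  if (nrow(x$sites) > 0) print(x$sites, row.names = FALSE)
  invisible(x)
}

#' Default 1-Mb toy genome with the seven-site cluster
#'
#' A 1-Mb circular genome with the replication origin at position 0 and the
#' native site cluster centred ~8 kb from it, emulating the ori-proximal
#' clustering of the natural system at desk scale.
#'
#' @param seed seed for the random background sequence.
#' @param with_sequence generate the nucleotide sequence?
#' @return A `parb_genome`.
#' @export
toy_genome <- function(seed = 101L, with_sequence = TRUE) {
  build_genome(1e6, default_parS_sites(), seed = seed, circular = TRUE,
               origin = 0, with_sequence = with_sequence)
}

#' Chromosome-scale 4.04-Mb genome configuration
#'
#' Geometry matching the natural chromosome: 4.04 Mb, circular, origin at 0,
#' native site cluster centred at +4,030 kb (~8 kb counter-clockwise of the
#' origin). Sequence generation is skipped by default at this scale; the
#' object is intended for insertion-library simulations, which only need
#' coordinates.
#'
#' @param seed seed (used only when `with_sequence = TRUE`).
#' @param with_sequence generate the 4-Mb sequence? Default `FALSE`.
#' @return A `parb_genome`.
#' @export
chromosome_scale_genome <- function(seed = 101L, with_sequence = FALSE) {
  sites <- default_parS_sites()
  sites$start <- sites$start - 8000 + 4030000  # re-centre cluster at +4030 kb
  build_genome(4.04e6, sites, seed = seed, circular = TRUE, origin = 0,
               with_sequence = with_sequence)
}

# Extract the subsequence [start, end] (0-based, inclusive) with circular wrap.
genome_subseq <- function(genome, start, end) {
  if (is.null(genome$sequence)) return(NA_character_)
  L <- genome$length
  start <- wrap_pos(start, L)
  end <- wrap_pos(end, L)
  if (end >= start) {
    substr(genome$sequence, start + 1, end + 1)
  } else {
    paste0(substr(genome$sequence, start + 1, L),
           substr(genome$sequence, 1, end + 1))
  }
}
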