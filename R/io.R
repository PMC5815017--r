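# External interfaces: FASTA via Biostrings, BED/bedGraph via rtracklayer,
# titrations as plain CSV, generator configs as YAML. Fragments that wrap the
# origin of a circular genome are exported with end > genome length and
# re-wrapped on import.

seqname_of <- function(genome) attr(genome, "name") %||% "genome"

# library-size lookup tolerating the YAML-1.1 reading of a bare `n:` key
# (which parsers coerce to a logical FALSE key)
cfg_n <- function(block, key, default) {
  block[[key]] %||% block$n %||% block[["FALSE"]] %||% default
}

#' Write / read a genome as FASTA
#'
#' @param genome a `parb_genome` carrying a sequence.
#' @param path FASTA file path.
#' @param name sequence name in the FASTA header.
#' @return `write_genome_fasta` returns `path` invisibly; `read_genome_fasta`
#'   returns a `parb_genome` (no site annotation).
#' @export
write_genome_fasta <- function(genome, path, name = "genome") {
  if (is.null(genome$sequence)) stop("genome carries no sequence")
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @param circular topology to record on the imported genome.
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  x <- Biostrings::readDNAStringSet(path)
  g <- build_genome(Biostrings::width(x)[1], seed = 0L, circular = circular,
                    with_sequence = FALSE)
  g$sequence <- as.character(x[[1]])
  attr(g, "name") <- names(x)[1]
  g
}

fragments_to_granges <- function(fragments, seqname) {
  GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = fragments$start + 1,
                              width = fragments$length),
    name = if ("source" %in% names(fragments)) fragments$source else "fragment"
  )
}

#' Write / read fragment libraries as BED
#'
#' BED is 0-based half-open; the `name` column carries the fragment source
#' label. Fragments wrapping a circular origin have `end` beyond the genome
#' length and are re-wrapped on import.
#'
#' @param fragments fragment `data.frame`.
#' @param path BED file path.
#' @param seqname chromosome name to write.
#' @export
write_fragments_bed <- function(fragments, path, seqname = "genome") {
  rtracklayer::export(fragments_to_granges(fragments, seqname), path,
                      format = "BED")
  invisible(path)
}

#' @rdname write_fragments_bed
#' @param genome_length used to re-wrap fragments crossing the origin.
#' @export
read_fragments_bed <- function(path, genome_length = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  start <- GenomicRanges::start(gr) - 1
  if (!is.null(genome_length)) start <- wrap_pos(start, genome_length)
  data.frame(start = start,
             length = GenomicRanges::width(gr),
             source = if (!is.null(gr$name)) gr$name else "fragment",
             stringsAsFactors = FALSE)
}

#' Write / read insertion libraries as BED (score = read count)
#'
#' @param library an `insertion_library`.
#' @param path BED file path.
#' @param seqname chromosome name.
#' @export
write_insertions_bed <- function(library, path, seqname = "genome") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = library$positions + 1, width = 1),
    name = library$label,
    score = library$counts
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_insertions_bed
#' @param genome_length genome length in bp (required on read).
#' @export
read_insertions_bed <- function(path, genome_length) {
  gr <- rtracklayer::import(path, format = "BED")
  structure(
    list(positions = GenomicRanges::start(gr) - 1,
         counts = as.integer(gr$score),
         total_insertions = sum(gr$score),
         label = if (length(gr)) gr$name[1] else "library",
         genome_length = genome_length),
    class = "insertion_library"
  )
}

#' Write a coverage or ratio track as bedGraph
#'
#' Per-base tracks are run-length compressed; binned tracks are written one
#' interval per bin. bedGraph is 0-based half-open.
#'
#' @param track a [coverage_track()] or `ratio_track`.
#' @param path bedGraph file path.
#' @param seqname chromosome name.
#' @export
write_track_bedgraph <- function(track, path, seqname = "genome") {
  if (inherits(track, "ratio_track")) {
    starts <- track$bin_starts
    ends <- pmin(starts + track$bin, track$genome_length)
    score <- track$log10_ratio
  } else if (!is.na(track$bin)) {
    starts <- (seq_along(track$values) - 1) * track$bin
    ends <- pmin(starts + track$bin, track$genome_length)
    score <- track$values
  } else {
    r <- rle(track$values)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    score <- r$values
  }
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = starts + 1, end = ends),
    score = score
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write binding-site calls as BED6 plus a summit/palindrome table
#'
#' The BED name field carries the called sequence (when available) and the
#' score the call height; a companion TSV (same path with `.tsv` appended)
#' reports summit coordinates and palindrome scores.
#'
#' @param calls call `data.frame` from [call_sites()].
#' @param path BED file path.
#' @param seqname chromosome name.
#' @param genome_length genome length (to wrap call ends).
#' @export
write_calls_bed <- function(calls, path, seqname = "genome",
                            genome_length = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = calls$site_start + 1,
                              end = calls$site_start + calls$length),
    name = if ("sequence" %in% names(calls)) calls$sequence
           else sprintf("call%d", seq_len(nrow(calls))),
    score = calls$height
  )
  rtracklayer::export(gr, path, format = "BED")
  utils::write.table(calls, paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read SPR titrations as CSV
#'
#' Columns: `concentration_nM`, `response_RU` and optionally `series_label`.
#'
#' @param series titration `data.frame`.
#' @param path CSV file path.
#' @export
write_titration_csv <- function(series, path) {
  out <- series
  lab <- attr(series, "label")
  if (!is.null(lab)) out$series_label <- lab
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_titration_csv
#' @export
read_titration_csv <- function(path) {
  x <- utils::read.csv(path)
  out <- data.frame(concentration_nM = x$concentration_nM,
                    response_RU = x$response_RU)
  if ("series_label" %in% names(x)) attr(out, "label") <- x$series_label[1]
  out
}

#' Run the synthetic-data generators from a YAML configuration
#'
#' The config must carry an explicit integer `seed` and a `genome` block
#' (`length`, `circular`, optionally `sites` with `start`/`sequence`/`kd`),
#' plus any of the experiment blocks `chip` (`n_fragments`, `spreading`,
#' `amplitude`, `background`), `idap` (`n_fragments`, `protein_conc`,
#' `background_prob`), `tn` (`n_insertions`, `zone_center`, `zone_width`,
#' `plateau`, `baseline`) and `spr` (`kd`, `rmax`, `noise_sd`). (A bare `n:`
#' key is also accepted, even though YAML 1.1 parsers read it as a boolean
#' key.) Outputs are written under `out_dir` as
#' FASTA/BED/CSV.
#'
#' @param config_path YAML file path.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list of the generated objects.
#' @export
simulate_from_config <- function(config_path, out_dir = ".") {
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$seed)) stop("config must set an explicit integer seed")
  seed <- as.integer(cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sites <- if (!is.null(cfg$genome$sites)) {
    s <- cfg$genome$sites
    planted_sites(vapply(s, `[[`, numeric(1), "start"),
                  vapply(s, `[[`, character(1), "sequence"),
                  vapply(s, `[[`, numeric(1), "kd"))
  } else default_parS_sites()
  genome <- build_genome(cfg$genome$length %||% 1e6, sites, seed = seed,
                         circular = cfg$genome$circular %||% TRUE)
  made <- list(genome = genome)
  write_genome_fasta(genome, file.path(out_dir, "genome.fasta"))
  if (!is.null(cfg$chip)) {
    occ <- simulate_occupancy(genome, spreading = cfg$chip$spreading %||% 2000,
                              amplitudes = cfg$chip$amplitude %||% 1,
                              background = cfg$chip$background %||% 0.02)
    made$chip <- simulate_chip_fragments(occ, cfg_n(cfg$chip, "n_fragments", 1e4),
                                         seed = seed + 1L)
    write_fragments_bed(made$chip, file.path(out_dir, "chip.bed"))
  }
  if (!is.null(cfg$idap)) {
    made$idap <- simulate_idap_fragments(
      genome, protein_conc = cfg$idap$protein_conc %||% 320,
      n = cfg_n(cfg$idap, "n_fragments", 1e4),
      background_prob = cfg$idap$background_prob %||% 0, seed = seed + 2L)
    write_fragments_bed(made$idap, file.path(out_dir, "idap.bed"))
  }
  if (!is.null(cfg$tn)) {
    lsc <- fitness_landscape(genome$length,
                             zone_center = cfg$tn$zone_center %||% 0,
                             zone_width = cfg$tn$zone_width %||% 0,
                             plateau = cfg$tn$plateau %||% 10,
                             baseline = cfg$tn$baseline %||% 1)
    made$tn <- simulate_tn_library(lsc, cfg_n(cfg$tn, "n_insertions", 1e4),
                                   seed = seed + 3L)
    write_insertions_bed(made$tn, file.path(out_dir, "insertions.bed"))
  }
  if (!is.null(cfg$spr)) {
    made$spr <- simulate_spr_titration(cfg$spr$kd %||% 30,
                                       cfg$spr$rmax %||% 100,
                                       noise_sd = cfg$spr$noise_sd %||% 0,
                                       seed = seed + 4L)
    write_titration_csv(made$spr, file.path(out_dir, "titration.csv"))
  }
  invisible(made)
}
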