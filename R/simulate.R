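#' Fragment-length samplers
#'
#' Named length distributions for simulated sequencing fragments. Each
#' constructor returns a function of `n` producing integer lengths >= 1.
#' Defaults used by the experiment simulators: sheared chromatin averages
#' ~150 bp (truncated normal), affinity-purification input is size-selected
#' to 200-500 bp (uniform).
#'
#' @param length,min,max,mean,sd distribution parameters in bp.
#' @return A sampler `function(n)`.
#' @name frag_samplers
NULL

#' @rdname frag_samplers
#' @export
frag_len_fixed <- function(length) {
  length <- as.integer(length)
  if (length < 1) stop("fragment length must be >= 1")
  function(n) rep.int(length, n)
}

#' @rdname frag_samplers
#' @export
frag_len_uniform <- function(min, max) {
  if (min < 1 || max < min) stop("need 1 <= min <= max")
  function(n) sample.int(max - min + 1L, n, replace = TRUE) + as.integer(min) - 1L
}

#' @rdname frag_samplers
#' @export
frag_len_truncnorm <- function(mean, sd, min = 1, max = Inf) {
  if (min < 1 || max < min) stop("need 1 <= min <= max")
  function(n) {
    out <- integer(0)
    while (length(out) < n) {
      x <- round(stats::rnorm(max(n - length(out), 64L) * 2L, mean, sd))
      out <- c(out, x[x >= min & x <= max])
    }
    as.integer(out[seq_len(n)])
  }
}

# Proposal machinery shared by the ChIP and IDAP simulators: uniform random
# starts (any start on a circular genome; starts keeping the fragment inside
# a linear one), lengths from the sampler.
propose_fragments <- function(m, genome_length, sampler, circular) {
  len <- sampler(m)
  if (circular) {
    start <- floor(stats::runif(m, 0, genome_length))
  } else {
    start <- floor(stats::runif(m) * (genome_length - len + 1))
  }
  list(start = start, len = pmin(len, genome_length))
}

#' Simulate a ChIP fragment library from an occupancy profile
#'
#' Immunoprecipitation is modelled as rejection sampling: fragments are
#' proposed with uniform random starts and sampled lengths, then retained with
#' probability equal to the *mean occupancy over the fragment*; proposals
#' repeat until `n` fragments are retained. The mean (rather than maximum)
#' occupancy keeps retention probabilities in [0, 1] and reproduces the
#' spreading-shaped coverage shoulders seen in the data.
#'
#' @param occupancy per-base occupancy profile (values in [0, 1]).
#' @param n number of retained fragments to produce.
#' @param frag_length_sampler a sampler from [frag_samplers]; default
#'   truncated normal, mean 150 bp.
#' @param seed integer seed; output is deterministic given the seed.
#' @param circular circular genome? Fragments may wrap the origin.
#' @param source label recorded on the fragments.
#' @return A `data.frame` of fragments with columns `start` (0-based),
#'   `length`, `source`, plus attributes `n_proposed` and `genome_length`.
#' @export
simulate_chip_fragments <- function(occupancy, n,
                                    frag_length_sampler = frag_len_truncnorm(150, 30, 50, 500),
                                    seed = 1L, circular = TRUE,
                                    source = "chip") {
  if (n < 1) stop("n must be >= 1")
  occ <- as.numeric(occupancy)
  if (all(occ == 0))
    stop("occupancy is identically zero: acceptance probability is zero everywhere")
  L <- length(occ)
  pref <- cumsum(c(0, occ, occ))  # circular prefix sums
  withr::with_seed(seed, {
    kept_start <- numeric(0)
    kept_len <- integer(0)
    n_prop <- 0
    p_est <- max(mean(occ), 1e-6)
    while (length(kept_start) < n) {
      m <- as.integer(min(2e7, ceiling((n - length(kept_start)) / p_est * 1.25) + 1000))
      pr <- propose_fragments(m, L, frag_length_sampler, circular)
      n_prop <- n_prop + m
      mean_occ <- (pref[pr$start + pr$len + 1] - pref[pr$start + 1]) / pr$len
      keep <- stats::runif(m) < mean_occ
      kept_start <- c(kept_start, pr$start[keep])
      kept_len <- c(kept_len, pr$len[keep])
      p_est <- max(sum(keep), 1) / m
    }
    out <- data.frame(start = kept_start[seq_len(n)],
                      length = kept_len[seq_len(n)],
                      source = source, stringsAsFactors = FALSE)
    attr(out, "n_proposed") <- n_prop
    attr(out, "genome_length") <- L
    out
  })
}

#' Simulate uniform input/control fragments
#'
#' The INPUT fraction of a ChIP experiment (or a bead-only control): fragments
#' sampled uniformly along the genome with no retention bias.
#'
#' @inheritParams simulate_chip_fragments
#' @param genome_length genome length in bp.
#' @export
simulate_input_fragments <- function(genome_length, n,
                                     frag_length_sampler = frag_len_truncnorm(150, 30, 50, 500),
                                     seed = 1L, circular = TRUE,
                                     source = "input") {
  withr::with_seed(seed, {
    pr <- propose_fragments(n, genome_length, frag_length_sampler, circular)
    out <- data.frame(start = pr$start, length = pr$len, source = source,
                      stringsAsFactors = FALSE)
    attr(out, "genome_length") <- genome_length
    out
  })
}

#' Simulate an in vitro affinity-purification (IDAP) fragment library
#'
#' Fragmented genomic DNA is incubated with the protein at `protein_conc` nM
#' and bound fragments are recovered. A proposed fragment is retained only if
#' it *fully contains* at least one planted site; its retention probability is
#' the 1:1 isotherm occupancy `protein_conc / (kd + protein_conc)` of the
#' strongest (lowest-Kd) contained site. Fragments containing no site are
#' retained with probability `background_prob` (bead-surface binding).
#'
#' @param genome a `parb_genome` with at least one planted site (unless
#'   `background_prob > 0`).
#' @param protein_conc protein concentration in nM.
#' @param n number of retained fragments.
#' @param frag_length_sampler length sampler; default uniform 200-500 bp.
#' @param background_prob retention probability of site-free fragments.
#' @param seed integer seed.
#' @return A fragment `data.frame` as in [simulate_chip_fragments()].
#' @export
simulate_idap_fragments <- function(genome, protein_conc = 320, n,
                                    frag_length_sampler = frag_len_uniform(200, 500),
                                    background_prob = 0, seed = 1L) {
  if (protein_conc <= 0) stop("protein_conc must be > 0 (nM)")
  if (n < 1) stop("n must be >= 1")
  sites <- genome$sites
  if (nrow(sites) == 0 && background_prob <= 0)
    stop("no planted sites and zero background probability: nothing can be retained")
  L <- genome$length
  theta <- protein_conc / (sites$kd + protein_conc)
  # site copies in unwrapped [0, 2L) coordinates for circular containment
  s_start <- sites$start
  s_end <- sites$start + sites$width
  if (genome$circular && nrow(sites) > 0) {
    s_start <- c(s_start, s_start + L)
    s_end <- c(s_end, s_end + L)
    theta <- c(theta, theta)
  }
  withr::with_seed(seed, {
    kept_start <- numeric(0)
    kept_len <- integer(0)
    n_prop <- 0
    p_est <- 0.01
    while (length(kept_start) < n) {
      m <- as.integer(min(2e7, ceiling((n - length(kept_start)) / p_est * 1.25) + 1000))
      pr <- propose_fragments(m, L, frag_length_sampler, genome$circular)
      n_prop <- n_prop + m
      fr_end <- pr$start + pr$len
      p <- rep(background_prob, m)
      for (i in seq_along(s_start)) {
        contained <- pr$start <= s_start[i] & fr_end >= s_end[i]
        p[contained] <- pmax(p[contained], theta[i])
      }
      keep <- stats::runif(m) < p
      kept_start <- c(kept_start, pr$start[keep])
      kept_len <- c(kept_len, pr$len[keep])
      p_est <- max(max(sum(keep), 1) / m, 1e-7)
    }
    out <- data.frame(start = kept_start[seq_len(n)],
                      length = kept_len[seq_len(n)],
                      source = "idap", stringsAsFactors = FALSE)
    attr(out, "n_proposed") <- n_prop
    attr(out, "genome_length") <- L
    out
  })
}

#' Simulate a transposon insertion library from a fitness landscape
#'
#' `n` insertion positions are drawn independently with probability
#' proportional to the per-base landscape weight (inverse-CDF sampling), then
#' aggregated to per-position counts.
#'
#' @param landscape per-base nonnegative weight vector
#'   (see [fitness_landscape()]).
#' @param n number of insertions.
#' @param seed integer seed.
#' @param label library label, e.g. `"parS_plus"` or `"parS_minus"`.
#' @return A list of class `insertion_library`: `positions` (0-based, sorted,
#'   unique), `counts` (reads per position), `total_insertions`, `label`,
#'   `genome_length`.
#' @export
simulate_tn_library <- function(landscape, n, seed = 1L, label = "parS_plus") {
  if (n < 1) stop("n must be >= 1")
  w <- as.numeric(landscape)
  if (any(w < 0)) stop("landscape weights must be >= 0")
  if (all(w == 0)) stop("landscape is identically zero: no viable insertion site")
  cdf <- cumsum(w)
  total_w <- cdf[length(cdf)]
  withr::with_seed(seed, {
    u <- stats::runif(n) * total_w
    pos0 <- findInterval(u, cdf)  # 0-based position
    tab <- table(pos0)
    structure(
      list(positions = as.numeric(names(tab)),
           counts = as.integer(tab),
           total_insertions = n,
           label = label,
           genome_length = length(w)),
      class = "insertion_library"
    )
  })
}

#' @export
print.insertion_library <- function(x, ...) {
  cat(sprintf("<insertion_library> %s: %s insertions at %s positions on %s bp\n",
              x$label, format(x$total_insertions, big.mark = ","),
              format(length(x$positions), big.mark = ","),
              format(x$genome_length, big.mark = ",")))
  invisible(x)
}

#' Simulate an SPR titration from the 1:1 binding isotherm
#'
#' The equilibrium response at protein concentration `c` is
#' `rmax * c / (kd + c)` plus additive zero-mean Gaussian noise. The default
#' concentration grid is the standard nine-point series used to estimate
#' binding constants (6.25-800 nM).
#'
#' @param kd dissociation constant in nM (> 0).
#' @param rmax maximal response in response units (> 0).
#' @param concentrations protein concentrations in nM.
#' @param noise_sd standard deviation of the response noise (RU).
#' @param seed integer seed.
#' @param label series label.
#' @return A `data.frame` with `concentration_nM` and `response_RU` and a
#'   `label` attribute (a `TitrationSeries`).
#' @export
simulate_spr_titration <- function(kd, rmax,
                                   concentrations = spr_default_concentrations(),
                                   noise_sd = 0, seed = 1L,
                                   label = sprintf("kd%.3g", kd)) {
  if (kd <= 0) stop("kd must be > 0 (nM)")
  if (rmax <= 0) stop("rmax must be > 0 (RU)")
  if (any(concentrations <= 0)) stop("concentrations must be > 0 (nM)")
  resp <- predict_response(kd, rmax, concentrations)
  if (noise_sd > 0) {
    resp <- withr::with_seed(seed, resp + stats::rnorm(length(resp), 0, noise_sd))
  }
  out <- data.frame(concentration_nM = concentrations, response_RU = resp)
  attr(out, "label") <- label
  out
}

#' The standard nine-concentration SPR titration grid (nM)
#' @export
spr_default_concentrations <- function() {
  c(6.25, 12.5, 25, 50, 100, 200, 400, 600, 800)
}
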