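---
title: "Models and methods: ParB binding-site calling, spreading quantification and parS-permissive zones"
author: "parbseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parbseq)
```

## The biological system and what the package computes

Bacterial chromosome segregation in organisms such as *Caulobacter
crescentus* depends on the ParA–ParB–*parS* partition system. *parS* is a
short (16-bp) palindromic, centromere-like sequence near the replication
origin; the ParB protein *nucleates* on *parS* and then *spreads* onto
flanking nonspecific DNA, building the partition complex that ParA segregates
to the daughter cells. Four sequencing/biophysics assays characterise this
system, and this package implements the computation behind each:

1. **IDAP-seq site calling** — *in vitro* DNA affinity purification with deep
   sequencing. Fragmented genomic DNA is incubated with the protein; only
   fragments containing a binding site are recovered. Sorting fragment 5'
   ends by strand and pairing the upper-strand and lower-strand count summits
   delimits the minimal binding sequence at single-nucleotide resolution
   (`strand_end_counts()`, `find_summits()`, `pair_summits()`,
   `call_sites()`).
2. **ChIP-seq occupancy quantification** — depth-normalised coverage tracks
   (RPBPM: reads per base pair per million mapped; RPKPM: per kb per
   million), fold enrichment over an input control, enriched-region calling,
   spreading extent, peak width and left/right asymmetry, and between-sample
   enrichment ratios (`fragment_coverage()`, `normalize_rpbpm()`,
   `bin_rpkpm()`, `fold_enrichment()`, `call_enriched_regions()`,
   `spreading_extent()`, `peak_width()`, `peak_asymmetry()`,
   `enrichment_ratio()`).
3. **SPR affinity estimation** — nonlinear least-squares fitting of the 1:1
   Langmuir isotherm $R(c) = R_\max\, c/(K_d + c)$ to equilibrium
   concentration–response titrations (`fit_kd()`, `predict_response()`,
   `percent_rmax()`).
4. **Tn-seq permissive-zone mapping** — comparative transposon insertion
   libraries (a *parS*-carrying transposon vs an empty one), binned to 10 kb,
   compared as $\log_{10}$ insertion-*frequency* ratios, with permissive and
   disfavoured zones and insertion hotspots called from the ratio track, and
   coordinate remapping across engineered chromosomal inversions
   (`bin_insertions()`, `log10_ratio_track()`, `call_zones()`,
   `call_hotspots()`, `remap_inversion()`).

Because the original genome-scale datasets are not redistributable at desk
scale, a first-class **synthetic-data module** generates toy genomes with
planted palindromic sites and simulates each experiment with the statistical
structure the analyses assume. All conclusions the tests draw are
parameter-recovery statements against this generator's ground truth.

## Coordinates and topology

All coordinates are 0-based, half-open internally; `BindingCall` intervals
are reported inclusive (`site_end` is the last base, so a 16-bp site has
`length = site_end - site_start + 1 = 16`). Bacterial chromosomes are
circular: interval arithmetic wraps modulo the genome length everywhere
(fragments, occupancy flanks, enriched regions, zones). A region or zone that
crosses the origin is reported with `end` greater than the genome length so
that `end - start` is always its width.

The default toy genome (`toy_genome()`) is 1 Mb, circular, origin at 0, with
seven planted sites: five strong ones (Kd tens of nM) clustered within 5 kb
centred ~8 kb from the origin, flanked by two weak sites (Kd ≥ 1 µM) —
mirroring the native arrangement in which the five strongest sites sit within
a 5-kb segment near *ori*. A 4.04-Mb configuration
(`chromosome_scale_genome()`) reproduces the natural geometry (cluster at
+4,030 kb) for insertion-library studies, which need only coordinates, not
sequence. The planted 16-mers are synthetic palindromes assembled around the
conserved GTGAAA half-site (`make_palindromic_site()`); the published site
sequences are available only as figure images, so the defaults are explicit
placeholders, not the natural sites.

## The synthetic-data generators

**Occupancy** (`simulate_occupancy()`): relative occupancy equals the site
amplitude over each site, decays linearly to the background over a per-side
spreading extent, and equals the background elsewhere; overlapping sites
combine by maximum. The data constrain only the *extent* of spreading (~2 kb
per isolated site, ~10 kb over the native cluster), not its shape; linear
decay is the simplest shape with a sharply defined support. At flank offset
$j \in 1..s$ the occupancy is $a - (a-b)\,j/(s+1)$, so the
strictly-above-background support of an isolated site is exactly
$w + 2s$ bp — which is what extent estimation is tested against.

**ChIP fragments** (`simulate_chip_fragments()`): fragments are proposed with
uniform starts and sampled lengths and retained with probability equal to the
*mean occupancy over the fragment* — smooth, bounded in [0, 1], and it
reproduces the spreading-shaped shoulders of real profiles. Sampling repeats
until the requested library size is retained, i.e. libraries are sequenced to
a fixed depth regardless of pulldown efficiency, as in practice. "Reads" are
whole fragments here: the short sequencing reads of the real protocol are an
upstream detail folded into the fragment abstraction, so coverage counts
fragment extents. Default length sampler: truncated normal, mean 150 bp
(sheared chromatin averages ~150 bp), bounds 50–500 bp.

**IDAP fragments** (`simulate_idap_fragments()`): a proposed fragment is
retained only if it *fully contains* a planted site, with probability given
by the 1:1 isotherm occupancy $[P]/(K_d + [P])$ of the strongest contained
site; site-free fragments are retained with a small background probability
(bead-surface binding; default 0). Default lengths: uniform 200–500 bp (the
size-selected sonication range). The containment rule is what makes
single-nucleotide resolution possible: no retained fragment's upper 5' end
can lie right of the site start.

**Insertion libraries** (`simulate_tn_library()`): positions are drawn
independently with probability proportional to a per-base fitness landscape
(`fitness_landscape()`: baseline, a permissive plateau, optionally a
terminus-proximal level). Sampling uses the inverse-CDF method on the
cumulative weight, which is the appropriate primitive at 4 million support
points.

**SPR titrations** (`simulate_spr_titration()`): exact isotherm responses at
the standard nine-point concentration series (6.25–800 nM) plus optional
additive Gaussian noise.

Every generator takes an explicit integer seed and is deterministic given it
(`withr::with_seed`, so the caller's RNG state is untouched).

**What the generator does not emulate:** sequencing errors and base
qualities, read-level duplicates, mappability variation, GC bias,
chromatin-accessibility bias in fragmentation, transposon target-site
preferences, and SPR drift/mass-transport artefacts. Passing tests therefore
demonstrate that the *analyses* recover what the *model* encodes; they do not
certify performance on real libraries with these additional noise sources.

## Summit detection under sampling noise

For a site $[s, s+w)$ probed with fragments of minimum length $m$, the
expected upper-strand 5'-end count is *flat* over $[s-(m-w), s]$ — every
start in that window admits the same number of containing lengths — and
drops to zero at $s+1$ (a fragment starting right of $s$ cannot contain the
site). The informative feature is therefore a plateau against a cliff, not a
unique maximum. On noise-free counts the rightmost position of maximal count
(upper strand; leftmost for the lower strand) is exactly the site edge, and
that is the tie-break `find_summits()` applies. On sampled counts the
literal argmax lands uniformly anywhere on the flat top, so the summit is
defined as the *directional edge of the plateau*: the rightmost (resp.
leftmost) position within the peak's support run whose count is at least
`plateau_frac` (default 0.25) of the peak count. The support run extends
over positive counts, bridging up to `gap_tol = 5` zero positions, which
keeps a weak site's run from dying on a single empty base while never
bridging the hundreds of empty bases that separate sites. With a quarter-
height membership rule, the probability that the true edge base of even a
weak site (expected count ~9 in the default seven-site study) fails the
plateau test is small, and an off-by-one summit still pairs within the
8–40-bp gap bounds, so detection is robust even where single-base exactness
is marginal.

`pair_summits()` pairs each upper summit with the nearest unused lower
summit whose inclusive gap lies in `[min_gap, max_gap]` (defaults 8 and
40 bp bracket a 16-bp site against end-count jitter), processing summits in
decreasing height order; unpaired summits are reported, never dropped.
`call_sites()` runs the whole pipeline with depth-scaled control subtraction
(control counts multiplied by the sample/control library-size ratio,
subtracted, floored at zero — switchable by passing no control) and a
default detection threshold of 5× the genome-wide median positive end
count, which tracks the nonspecific background level rather than a fixed
count.

## ChIP analysis choices

**Units.** RPBPM is `raw / (total_mapped / 1e6)`; RPKPM additionally sums
1-kb bins. The final partial bin of a genome not divisible by the bin width
is kept and flagged.

**Peak width** is support width above background, not FWHM: for a
nucleation-only binder probed by fragments of fixed length $L$ fully
containing a $w$-bp site, the coverage support is exactly $2L - w$
(fragments can start up to $L-w$ left of the site and end up to $L-w$ right
of it). With $L = 208$, $w = 16$ this is the characteristic 400-bp peak of a
site-specific, non-spreading binder — which is why support width, rather
than any half-maximum convention, is the width definition used throughout.

**Region calling** thresholds the fold-enrichment track at ≥ 2 over the
input, merges runs separated by ≤ 500 bp and discards runs < 200 bp. The
2-fold default is a choice (the data show "significant enrichment above
background" without quantifying it) and is exposed as a parameter. Per-base
fold enrichment at realistic depths (tens of fragments per base) is noisy
enough that isolated bases cross any fixed threshold, and because merging
precedes the minimum-run filter, single-base spurs can chain into a
neighbouring region; `call_enriched_regions()` therefore accepts an odd
moving-average window (`smooth`; the extent studies use 201 bp, on the order
of the fragment length). The expected signal is locally linear at the
threshold crossing, so smoothing suppresses the spurs without shifting the
expected boundary.

**Backgrounds are study conditions.** The nonspecific-capture level of a
simulated ChIP library is the one generator parameter the source data do not
pin down, and the two ChIP studies sit in different regimes, so each study
fixes it explicitly:

* *Extent mapping* (`study_single_site_extent()`, `study_cluster_extent()`)
  uses background 0.02. Extent recovery through a fixed 2-fold cutoff
  degrades as background grows — the crossing point moves from the edge of
  the occupied span into the flank (at background $b$ the flank is cut where
  occupancy falls to twice the genome-mean occupancy, i.e. a fraction
  $\approx (1-2b)/(1-b)$ of the span) — so extent experiments are modelled
  as high-specificity IPs.
* *Abundance comparison* (`study_wt_mutant_ratio()`) uses background 0.15
  for both libraries. Real in-vivo ChIP libraries are background-dominated
  (in-peak fractions of a few percent are typical; the simulated wild type
  has ~4%), and it is precisely in that regime that the region-mean signal
  ratio between matched-depth libraries reflects the occupancy difference:
  with a common background mass $bG$ dominating both normalisations, the
  mean signal over a window $R$ is proportional to (above-background
  occupancy area in $R$) $+\ bR$, and the wild-type (spreading, amplitude
  1.0) to mutant (nucleation-only, amplitude 0.2 — the spreading-deficient
  protein is also less abundant in vivo) ratio over the ~10-kb cluster
  window is ~5. This ratio is genuinely background-sensitive: at background
  0 two matched-depth libraries have identical region means regardless of
  amplitude (fixed-depth sequencing renormalises away any overall
  efficiency), and the comparison is only meaningful against a shared
  nonspecific floor. Both backgrounds were fixed from these analytic
  expectations before any simulation was scored, and are not tuned.

**Asymmetry** is the ratio of above-background signal area over symmetric
5-kb flank windows left and right of the site; spreading in these systems is
often unequal on the two sides of the site (transcription and other bound
proteins get in the way), and this statistic quantifies it with 1 as perfect
symmetry. A zero right-side area raises a typed condition rather than
returning an arbitrary number, as do an anchor outside all regions
(`parbseq_undefined_extent`) and a zero denominator mean
(`parbseq_undefined_ratio`).

## SPR fitting choices

The model is the 1:1 Langmuir steady-state isotherm — the stated
stoichiometry is a single protein dimer per immobilised duplex — fitted by
unweighted Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) over
$(K_d, R_\max)$, both constrained positive. Initial values: $K_d$ at the
concentration whose response is nearest half the maximum observed response;
$R_\max$ at 1.1× the maximum response. The fit reports the residual sum of
squares, the asymptotic standard error of $K_d$, and an explicit convergence
flag; non-convergence never returns a silent bad fit. Kinetic (on/off-rate)
sensorgram analysis and multi-site or Hill models are out of scope. The
invariances that matter — response scaling moves only $R_\max$,
concentration unit changes rescale $K_d$ exactly — are asserted in the test
suite, and noise-free nine-point titrations at the strong (30 nM) and weak
(114 nM) affinities are recovered to optimiser precision.

## Tn-seq choices

Insertion *frequencies* (count / library total) are compared, not raw
counts, so unequal sequencing depths cancel; the *parS*-carrying library is
the numerator. A pseudocount of one insertion per bin avoids log of zero.
The permissive-zone threshold is $\log_{10}$ ratio ≥ 0 — the *parS*⁺
transposon inserted at least as frequently as the empty one — because the
source data delimit the zone by eye; zones need ≥ 3 consecutive 10-kb bins
and may bridge one off-threshold bin, and zone calling is circular-aware
(the native-cluster zone wraps the origin of the chromosome-scale genome).
Hotspots are bins exceeding the track median by 4 MAD-based robust standard
deviations, with adjacent hotspot bins merged; a constant track yields no
hotspots and a degenerate-scale flag. Counts-weighted binning is the
default; unique-insertion-site analysis amounts to setting all counts to 1
on input. Inversion remapping reflects $[l, r)$ via
$x \mapsto l + r - 1 - x$, an involution that preserves adjacency inside the
segment, matching the reconstructed-reference convention used for inverted
strains.

## Problem sizes and determinism

The bundled studies run at desk scale by design: 1-Mb (analysis) and 4.04-Mb
(insertion) toy genomes; 100,000–200,000 fragments or insertions per
simulated library; 16,610 fragments in the exhaustive site-calling fixture;
nine-point titrations. At these sizes every recovery statement in the test
suite has comfortable Monte-Carlo margin (e.g. ~1,000 mutant-library
fragments inside the comparison window give the enrichment ratio a ~3%
sampling error against a ±15% acceptance band). All stochastic results are
reproducible from explicit integer seeds.

## Known limitations

* The generator's noise model is idealised (see above); thresholds tuned on
  it (2-fold regions, 5× median end-count summit floor) will need
  re-examination on real libraries.
* Summit calling assumes the containment cliff is the dominant feature; a
  binder with strong sequence-biased fragmentation around its site could
  shift summits by a few bases.
* The WT/mutant enrichment ratio depends on the nonspecific background
  level; it is reported under a stated background, not as a
  background-free quantity.
* No multiple-testing machinery over Tn-seq bins, no gene-level
  essentiality statistics, no motif-matrix learning, and no read-level
  (FASTQ/BAM) processing: the package consumes aligned coordinates.
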