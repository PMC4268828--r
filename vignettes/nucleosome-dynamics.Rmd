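---
title: "Quantifying nucleosome dynamics between MNase-seq time points"
author: "nucleodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleosome dynamics between MNase-seq time points}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A cell responding to an extracellular signal reorganizes its chromatin
within minutes: nucleosomes slide, are evicted or deposited, and the
accessibility of regulatory DNA changes long before steady-state
transcription does. MNase-seq — micrococcal-nuclease digestion of
chromatin to mononucleosomes followed by paired-end sequencing — reads
this landscape out: each sequenced fragment of roughly 147 bp covers one
nucleosome, and the fragment *midpoint* estimates the dyad, the centre
of the wrapped DNA.

`nucleodyn` compares two MNase-seq time points (an unstimulated
reference `t1` and a stimulated sample `t2`) and asks, at several
genomic scales:

* Which windows of the genome lost or gained nucleosome occupancy?
* Which individual nucleosomes moved, and by how much?
* How do occupancy changes distribute over gene bodies of up-regulated,
  down-regulated and constitutively expressed genes?
* Are transcription-factor binding sites and chromosomal contacts
  (viewpoint 3C/4C profiles) preferentially located in
  nucleosome-depleted domains?

Because real stimulation experiments ship hundreds of millions of
reads, the package also contains a first-class synthetic-data generator
that produces the same statistical structures at desk scale, with a
ground-truth table for recovery testing. Every empirical claim the
package makes about itself is recomputed by its test suite and by
`scripts/acceptance.R`.

# The windowed occupancy statistic

Each chromosome is tiled into non-overlapping windows
$w_1, \dots, w_n$ of constant size $|w|$ (5 kbp by default; terminal
remainders are kept but flagged). With $r_i$ and $s_i$ the
fragment-midpoint counts of the two libraries in window $i$, the
statistic is the centred log-ratio

$$ q_i = \log_2 \frac{r_i + c}{k\, s_i + c}, \qquad
   \lVert q_i \rVert = q_i - \bar q , $$

where $c$ is a pseudocount (default 0.5), $k = \sum_i r_i / \sum_i s_i$
rescales the later library to the depth of the earlier one, and
$\bar q$ is the mean over scored windows, so the centred values are
mean-zero by construction. Windows with fewer than $m$ combined
depth-adjusted reads (default 20) are masked `low_coverage` and take no
part in the mean, the null, or the labels.

Three choices deserve comment:

* **Depth normalization before the pseudocount.** Centring alone
  absorbs a uniform depth difference only when $c = 0$; with a
  pseudocount, $\log_2((r+c)/(3s+c))$ is *not* a constant shift of
  $\log_2((r+c)/(s+c))$, and the coverage mask ($r_i + s_i < m$) also
  moves. Rescaling $s_i$ by $k$ first makes the entire pipeline —
  centred values, p-values, masks, labels — exactly invariant under
  scaling either library, which is the invariance the statistic is
  supposed to have. At equal depths $k = 1$ and the formula reduces to
  the plain ratio. `logRatio(..., normalize = FALSE)` restores the
  unnormalized form.
* **Log base 2.** The base only rescales $q$ and cancels in the
  empirical null; base 2 keeps the display tracks in the familiar
  log2 fold-change units.
* **Sign convention.** $q$ puts the *earlier* time point in the
  numerator, so a positive centred value means lower occupancy later —
  depletion. Display tracks (`foldChangeTrack()`) are negated so that
  depletion plots downward, the usual browser orientation, and smoothed
  with a centred running mean (default span 5 windows, shrinking at the
  edges).

## The empirical null from inert regions

Counting noise, digestion efficiency and mappability vary along the
genome, so the null distribution of $\lVert q_i \rVert$ is estimated
empirically rather than assumed: windows lying entirely within
*transcriptionally inert* regions — regions with no expressed gene and
negligible RNA signal, supplied as a BED-style interval set — are taken
to fluctuate for technical reasons only. Their centred values form the
null sample (both signs retained), and each window is scored against
its empirical CDF $N_\mathrm{cum}$ with one-sided p-values

$$ p_\mathrm{right}(x) = \frac{1 + \#\{\text{null} \ge x\}}{1 + m_0},
   \qquad
   p_\mathrm{left}(x) = \frac{1 + \#\{\text{null} \le x\}}{1 + m_0}. $$

The add-one smoothing keeps p-values in $(0, 1]$ and converges to
$1 - N_\mathrm{cum}(x)$ as the null grows. The right tail tests
depletion at the later time, the left tail enrichment; the two tails
are treated as separate one-sided tests. A floor on usable inert
windows (default 100) and a degeneracy check (all null values
identical) guard against meaningless nulls. For synthetic landscapes
the generator emits ground-truth inert intervals; for fully inert
calibration genomes `inert = NULL` admits every non-partial window.

The p-value floor $1/(1+m_0)$ has a practical consequence for multiple
testing: Benjamini–Hochberg at level $\alpha$ can only reject rank-$j$
windows with $p \le j\alpha/n$, so isolated single-window events are
undetectable under BH when the null is small relative to the window
count. Broad or numerous events — the regime this analysis targets —
are unaffected. Both `correction = "BH"` (default, rejection at
adjusted $p \le \alpha$) and `correction = "none"` (raw $p < \alpha$)
are provided.

## Multi-scale domains

`multiscaleDomains()` reruns the identical statistic at 5, 25, 50 and
100 kbp from the same midpoints. Broad occupancy changes remain
significant at every scale, while sub-window events dilute away at
coarse scales (a 5-kbp, 0.5× depletion contributes only
$\log_2(1/0.975) \approx 0.04$ to a 100-kbp window, within the null's
spread at typical depths) — the package's tests verify both behaviours.

# Nucleosome dyads and repositioning

Single-nucleosome positions are called from fragment midpoints in three
steps:

1. **Kernel density.** Midpoint counts per bp are convolved with a
   discrete Gaussian (sd = bandwidth, default 30 bp; unit-sum kernel,
   truncated at 4 sd with tails folded back, so total mass equals the
   midpoint count). The convolution runs as an FFT padded to a
   2–3-smooth length; arbitrary lengths can be near-prime and make the
   FFT quadratic.
2. **Greedy exclusion.** Local maxima (plateaus collapse to their left
   edge) are visited in order of decreasing height, ties broken
   leftmost; any maximum closer than `minSeparation` (default 147 bp,
   one nucleosome footprint) to an accepted call is suppressed.
3. **Centroid refinement.** The reported dyad is the intensity-weighted
   centroid of the raw midpoints within ±73 bp of the summit. The
   summit alone is quantized to the bp grid and carries the kernel's
   positional noise; the centroid is a sub-grid estimate whose error
   shrinks as $\sigma/\sqrt{n}$ with the local fragment count, which is
   what makes a 10-bp shift criterion meaningful at realistic coverage.

Calls from the two time points are paired by **mutual nearest
neighbour** within ±73 bp — half a footprint, so matches cannot jump
across a phased array. Matched pairs with $|\Delta\text{dyad}| > 10$ bp
are `repositioned`, others `stable`; unmatched reference calls are
`lost`, unmatched later calls `gained`. Swapping the two time points
swaps lost and gained and preserves shifts. `unmaskedRegions()` exports
one merged footprint (±73 bp) around every repositioned or lost dyad —
the DNA newly exposed relative to the reference — for external
annotation.

# Metagene profiles and gene classes

`classifyGenes()` reproduces the threshold classification of
two-time-point expression counts: median-of-ratios size factors
(`DESeq2::estimateSizeFactorsForMatrix`), log2 fold-change on
normalized counts, and classes *up* (> 0.6), *down* (< −0.6),
*constitutive* (|log2FC| ≤ 0.01), with genes at or below 100 raw reads
in either library left unclassified. No dispersion test is performed;
the classification is deliberately the printed-threshold rule.

`metageneProfile()` aligns genes at TSS and TTS: 5-kbp flanks in 50-bp
bins flank a gene body whose 50-bp window counts are rescaled onto a
fixed 100-bin axis. The rescaling is **area-weighted averaging** (each
output bin averages the input windows it overlaps, with fractional
weights) rather than point-sampled interpolation: point sampling is
exact on flat signal but can drop a one-window feature entirely when
downscaling, whereas area weighting conserves mass. Minus-strand genes
are reversed so the TSS is always leftmost; flank bins reaching past a
chromosome end are masked and simply contribute no genes to those bins.
Profiles are raw per-bin sums by default; `perMillion = TRUE` scales to
reads per million for cross-library display.

# Interval association

`overlapEmbedded()` calls a peak *embedded* in a domain set when the
union of domains covers at least 25% of the peak's length (the
fraction is relative to the peak by default; a domain-relative variant
is available). `annotateLocation()` classifies intervals by their
midpoint as promoter (within ±1 kbp of a TSS, taking precedence),
intragenic, or intergenic. `fisherAssociation()` reports the sample
cross-product odds ratio and the exact conditional two-sided p-value
(`fisherExactP()`: the hypergeometric probabilities of all tables with
the observed margins, summed over tables no more probable than the
observed one, with the customary $1 + 10^{-7}$ relative tie guard).
The unit tests check this against both `stats::fisher.test` and an
independent log-choose enumeration. `motifScan()` counts occurrences
of an IUPAC consensus (default the NF-κB motif `GGRRNNYYCC`, which is
its own reverse complement) on both strands via
`Biostrings::matchPattern(fixed = FALSE)`; it is an occurrence
counter, not an enrichment statistic.

# Contact domainograms

A viewpoint contact profile is a set of restriction-fragment ends with
read counts. Reads are **binarized** (an end is contact-positive iff it
carries ≥ 1 read), which removes depth dependence entirely. Windows on
a geometric ladder of 12 sizes from 2 to 200 kbp, slid in steps of a
tenth of their size, are scored as

$$ \text{score} = \frac{\text{positive ends in window} /
   \text{ends in window}}{\text{background rate}}, $$

with the background rate estimated from 3,000 fragment ends sampled
uniformly without replacement (all ends when fewer exist) and windows
with fewer than 3 ends masked. Significance comes from permutation:
the binary labels are shuffled over the ends (the background re-sampled
from the same indices each round, mirroring the observed scoring), and
the threshold is the smallest observed score $t$ with

$$ \widehat{\mathrm{FDR}}(t) =
   \frac{\text{mean permuted windows} \ge t}
        {\text{observed windows} \ge t} < 0.01 . $$

Profiles that are all-positive or all-negative admit no threshold and
return an empty significant set with a warning. The ladder geometry,
the $w/10$ step, the 3-end mask and this FDR estimator are this
package's explicit realization of the verbal description of the
domainogram procedure; the original implementation is not reproduced.
`contactsVsDepletion()` then tests, by Fisher's exact test on window
midpoints, whether significant contact windows fall in
nucleosome-depleted windows more often than non-significant ones.

# The synthetic-data generator

The generator plants exactly the structures the statistics must
detect, and nothing else:

* **Landscape.** A homogeneous dyad-weight background of one
  nucleosome per repeat length (NRL, default 190 bp); within each
  expressed gene body, a phased array of unit-mass Gaussian dyads
  (sd 10 bp) spaced one NRL apart starting half a repeat downstream of
  the TSS. Tracks are deterministic given the gene set.
* **Events.** Depletion/enrichment events multiply the track in an
  interval by a factor (default 0.5 for depletions), changing its mass
  by exactly that factor; shift events translate the track (edges
  clamped). Overlapping events are rejected as contradictory. The
  magnitudes are package choices — the motivating experiments report
  relative tracks, not planted effect sizes.
* **Fragments.** Per chromosome, a Poisson number of fragments with
  mean occupancy × track mass (occupancy = expected fragments per
  nucleosome, default 30); midpoints drawn proportional to the track;
  lengths normal (147 ± 10 bp) clipped at 50 bp; fragments shifted
  inward at chromosome ends. Fragment midpoints, not 5′ ends, carry
  the dyad signal, matching mononucleosome libraries.
* **Annotations.** Non-overlapping genes with expression classes in
  given fractions; true log2 fold-changes respect the class thresholds
  (constitutive genes change by exactly 0); the count table adds
  Poisson noise on top. TF peaks are placed inside depletion events
  with probability $\mathrm{odds} \cdot D / (\mathrm{odds}\cdot D +
  1 - D)$ for depleted genome fraction $D$ — the closed-form odds
  construction the association tests recover. Inert regions are the
  genome minus expressed genes and events (with buffers), mirroring an
  RNA-seq-derived inert set. Contact targets sit inside depletion
  events when any exist.
* **Contacts.** Each fragment end is positive with the background rate,
  or the signal rate inside a contact target; positive ends get
  1 + Poisson(2) reads.

Randomness always flows through one explicitly seeded, private PRNG
stream per generator call (the caller's random state is restored), so
identical seed and parameters give byte-identical output files; the
pipeline derives per-stage seeds from a single master seed and proves
reproducibility by checksum in its manifest.

**What the generator does not emulate** — and therefore what passing
recovery tests do *not* demonstrate about real data: sequence-dependent
MNase bias and GC effects, mappability gaps, replicate-to-replicate
overdispersion beyond Poisson, NRL heterogeneity across chromatin
states, partial digestion (di-/tri-nucleosome fragments), and
inter-chromosomal contacts. The tests show the estimators are correct
and calibrated under the stated model, not that the model captures
every property of chromatin.

# Validation scales and numerical conventions

The test suite and `scripts/acceptance.R` exercise the pipeline at
sizes chosen to make every recovery property measurable with
comfortable margins while keeping a full run in minutes on one CPU:
a 10-Mbp genome (2,000 windows of 5 kbp) for null calibration
(~210 reads/window), domain recovery (20 planted 25-kbp 0.5×
depletions at 30 fragments/nucleosome) and TF association (200 peaks
at 4× odds in a 20% depleted genome); a 400-kbp phased array
(~2,000 nucleosomes at 50 fragments each) for shift classification;
20–50 seeded 1-Mbp contact profiles of 2,000 ends for FDR control; and
a 3-Mbp, 40-gene genome for metagene ordering.

Conventions used throughout: coordinates are 0-based half-open in all
text formats and events (BED semantics) and 1-based closed inside
GRanges, converted only at format boundaries; the midpoint of an
even-length interval rounds down; bedGraph output never merges
equal-valued windows, so a round trip preserves window identity; ties
in dyad calling break leftmost; empirical p-values use add-one
smoothing; BH rejects at adjusted $p \le \alpha$ while raw mode uses
$p < \alpha$; all derived seeds stay below $2^{31}$.

# Known limitations

* No replicate-aware dispersion model: windows are compared by counts
  alone, as in the original analysis design.
* No GC/MNase-bias correction; on real data, bias that differs between
  time points would masquerade as occupancy change.
* The dyad caller is a transparent stand-in for peak callers used in
  the motivating work, built so the >10 bp repositioning criterion is
  testable without third-party binaries; it does not reproduce their
  exact scoring.
* BH detection of isolated single-window events is limited by the
  empirical-null p-value floor (see above); raw-p mode exists for
  that regime.
* The domainogram considers intra-chromosomal contacts of one
  viewpoint at a time.

# A minimal session

```{r demo}
library(nucleodyn)

spec <- landscapeSpec(chromLengths = c(chrS1 = 2e6),
                      baseOccupancy = 20, seed = 1)
sim <- simulateExperiment(spec, nGenes = 20, nDepletion = 6,
                          eventWidth = 25000, nPeaks = 60,
                          tfEnrichmentOdds = 4)
res <- occupancyLLR(sim$t1, sim$t2, genome = specSeqinfo(spec),
                    windowSize = 5000, inert = truthInert(sim$truth))
table(windowLabels(res))
depletedWindows(res)

calls0 <- callNucleosomes(fragmentMidpoints(sim$t1))
calls1 <- callNucleosomes(fragmentMidpoints(sim$t2))
events <- matchDyads(calls0, calls1)
table(events$status)
```

The full orchestration — simulation, occupancy, multi-scale domains,
repositioning, metagene, peak embedding, contacts, manifest — is
`runPipeline(outdir, seed = 1)`, and `pipelineReport(outdir)` restates
a finished run's summary from its files alone.
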