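---
title: "Calibrated detection of low-prevalence variants in ultra-deep amplicon sequencing"
author: "ampliCall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated detection of low-prevalence variants in ultra-deep amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliCall)
```

## The measurement problem

A subclonal tumor mutation present in 1–5% of the DNA molecules of a
sample produces, at a given base, an alternative-allele fraction of the
same order as the raw substitution error rate of
sequencing-by-synthesis instruments (0.05–1%, depending on cycle and
substitution type). Raw allele fractions are therefore uninterpretable
at these prevalences without a position-resolved error model.

Amplicon sequencing has a structural advantage here: because every read
of an amplicon starts at the same genomic coordinate, each genomic base
always occupies the same sequencing cycle. The error rate at that exact
(direction, cycle, reference→alternative) stratum can then be measured
empirically — provided a *calibration sample* whose true variant content
is known is sequenced in the same run, so that the measurement reflects
the run's own chemistry.

`ampliCall` implements this design end to end: error-model training,
prefiltering, per-direction binomial testing, cross-direction
combination, data-driven threshold selection, somatic classification,
and a simulator that reproduces the calibration experiment
synthetically.

## Data model

- **AmpliconDesign** — one record per amplicon: a target interval
  flanked by two primer spans (all coordinates 1-based inclusive, the
  R/Bioconductor convention; files are 1-based too, so no conversion
  happens at I/O). Sequencing starts at the outer primer ends; the
  package fixes the informative read length at 122 cycles. With the
  default geometry (20 bp primers + 160 bp target = 200 bp amplicon)
  every target base is reachable within 100 cycles from at least one
  direction, so no base is lost to the read-end filter by design.
- **PileupTable** — one row per (amplicon, direction, position): read
  position, reference base and A/C/G/T counts of base calls with PHRED
  quality strictly greater than 20. Forward and reverse observations of
  the same genomic base are deliberately kept separate; the two
  directions have independent error structure and are only combined at
  the statistics stage. When built from alignments, reads containing
  insertions or deletions are excluded (the statistics target
  substitutions only), clipped reads are excluded, and each read is
  assigned to the amplicon whose sequencing start matches its 5'
  alignment start exactly (a configurable tolerance exists for panels
  with ragged starts; the strict default is logged so users can see
  what was dropped).

## The error model

Training uses only plausibly invariant columns: known polymorphic
positions (the calibration SNPs and any catalogued variants of the pool
members) are masked outright, columns with non-reference fraction above
5% are dropped (likely unannotated variants or PCR errors upstream of
sequencing), and columns under 10 reads are dropped. The remaining
observations are pooled into 2 × 122 × 12 bins — direction, read
position, and ordered substitution type (4 references × 3
alternatives) — and each bin's raw rate is total mismatches over total
depth.

Bins whose depth falls short of the average bin depth (computed over the
full grid) are smoothed within their (direction, reference, alternative)
stratum: neighbors at read positions k±1, k±2, … are accumulated until
the summed depth exceeds the average, and the smoothed rate is the
normalized weighted mean

$$E_k = \frac{\sum_j e_j\, n_j\, r_j}{\sum_j n_j\, r_j},
\qquad r_j = \frac{1}{|j-k|+1},$$

so the center has weight 1 and the first and second neighbors 1/2 and
1/3. The normalization by $\sum n_j r_j$ is what makes the expression a
rate; the smoothed value is always a convex combination of the
contributing raw rates (property-tested). Boundary positions simply
accumulate outward on the available side. Strata with no data anywhere
receive a floor rate — half the smallest positive smoothed rate in the
model (1e-6 if the model is degenerate) — and the lookup also floors
zero rates, so the binomial test below is always well defined. The
choice of *half* the smallest observed rate is a conventional
pseudo-rate: small enough not to mask real signal, large enough to keep
p-values finite.

## Candidate statistics

Four prefilters run before any test; each removed position keeps its
flag, so positions are conserved through the pipeline (a property the
tests assert):

1. **Primer positions** are synthesized primer, not template, and are
   removed.
2. Positions with pooled (both directions) non-reference fraction
   **below 0.2%** are removed. The assay is specified for ≥ 1%
   prevalence; a signal five times weaker than that specification is
   noise with overwhelming probability, and removing it early bounds
   the number of tests. The cutoff is *strict*: exactly 0.2% survives.
3. Positions covered by a **single direction beyond read position 100**
   are removed — late cycles carry the highest error rates and have no
   second direction to check them.
4. At dual-direction positions where the directions **disagree** about a
   candidate allele, one direction's evidence is rejected: F is rejected
   when Cov(F) < 0.1·Cov(R) (strict) or when Pos(F) > Pos(R), and
   symmetrically for R. "Disagree" is operationalized as: the allele's
   fraction exceeds the 0.2% floor in exactly one direction. This was a
   genuinely open definition; the fraction-based reading is the one that
   needs no statistics before the statistics stage.

Each remaining non-reference allele is tested separately against its own
(direction, read position, ref→alt) rate — the stratification of the
error model implies per-allele tests — with the inclusive binomial upper
tail $P(B \ge X)$, $B \sim \mathrm{Binomial}(N, E)$. The inclusive
convention gives $p = 1$ at $X = 0$, which keeps ranking coherent.
Directions are combined with a depth-weighted Stouffer Z-score,

$$Z = \frac{N_f Z_f + N_r Z_r}{\sqrt{N_f^2 + N_r^2}},
\qquad Z_i = \Phi^{-1}(1 - p_i),$$

falling back to the single available direction's p-value otherwise.
Depth weights are used as-is ($w_i = N_i$); weighting by $\sqrt{N_i}$
would be the variance-optimal choice if per-direction Z-scores carried
equal information per read, but depth weighting follows the method's
definition and the difference is immaterial at the depths involved — the
choice is surfaced here rather than as a second code path. p-values are
clamped to [1e-300, 1] (and to 1 − 1e-16 before the quantile transform)
to keep Z finite; the clamp only matters for signals that are already
astronomically significant. A position is reported once, for its
best-supported allele (smallest combined p, ties broken by larger pooled
count, then alphabetically).

The reported prevalence is the pooled count ratio over accepted
directions only.

## Threshold selection and the tested sample

Nominal p-values are *not* used for calling. The calling pass is first
run on the calibration sample itself; every distinct candidate p-value
is tried as a threshold (call iff p ≤ t, inclusive, so the optimum is
always realizable), and the threshold maximizing the Matthews
correlation coefficient against the calibration truth is kept, with
ties resolved toward the most stringent threshold. MCC is the right
objective here because the classes are extremely imbalanced (~200 true
variants against ~24,000 invariant bases); its zero-denominator cases
are defined as 0. The selection is verified against an exhaustive
cut-point scan on randomized instances.

Calling the tested sample adds three guards: positions whose collapsed
(direction-merged) depth falls strictly below the calibration sample's
nearest-rank 5th depth percentile are excluded (coverage discrepancies
between the runs would otherwise bias the comparison; nearest-rank is
the inverse-ECDF percentile, type 1 in R's nomenclature); candidates
above the MCC threshold are flagged; and, when at least three control
(germline blood) samples are available, positions recurrently noisy in
three or more controls are masked. A control position is noisy when its
non-reference count is binomially improbable (p < 5e-4, the
per-amplicon Bonferroni-corrected level, taken as printed rather than
recomputed) under the local error rate pooled from the 10 flanking
positions on each side; windows truncated below 5 available flanking
positions per side make the position unassessable rather than silently
mis-measured.

Somatic classification compares each tumor call with the matched
germline sample analyzed with the same artifacts: somatic requires
germline collapsed depth strictly above 10, no germline call of the
allele, and germline allele ratio strictly below 20% (pooled across
directions, consistent with the prevalence estimator). Xenograft
samples additionally drop calls at host/graft genome mismatch positions
(exact-position semantics), consumed as a precomputed list — deriving it
from a whole-genome alignment is out of scope.

## The simulator: what it emulates, and what it does not

The simulator generates the calibration experiment at column (count)
level rather than read level: per (amplicon, direction) a Poisson depth
around the amplicon's efficiency, constant along the read because every
read spans all retained cycles; per column, variant molecules drawn
binomially at the expected prevalence, then every molecule corrupted by
the profile's (direction, cycle, ref, alt) rate via chained binomials.
Column-level simulation preserves all downstream statistics (the
pipeline never looks inside reads) at a fraction of the cost; what it
cannot emulate are read-level artifacts — chimeric reads, alignment
errors, PCR duplicates, strand-specific context effects — so passing
tests demonstrate the statistical machinery, not robustness to
artifacts the error model does not describe.

Choices a practitioner would want stated:

- **Mixing design:** four donors at proportions 1/5/20/74%, rotated
  across pools so each donor sits at each proportion once; 200 SNPs,
  each homozygous-alternative in exactly one donor. Heterozygous
  singleton positions (expected prevalence 0.5%) are flagged
  sub-detectable and excluded from sensitivity denominators, mirroring
  the assay's 1% design floor.
- **Coverage dispersion:** amplicon efficiencies are lognormal with
  log-sd 0.52, calibrated so ~82% of amplicons fall within 0.5–2× of
  the mean — the uniformity of a well-behaved microdroplet panel.
  Efficiencies are drawn once per experiment and shared across its
  samples (amplification efficiency belongs to the primer pair) with a
  small per-sample lognormal jitter (log-sd 0.1); coverage between
  samples of a run is reproducible, and fully independent coverage
  would be the wrong model.
- **Error profiles:** the GAII-like preset draws per-substitution base
  rates in 0.05–0.3% and inflates A/T-reference rates linearly up to
  threefold after cycle 100; the MiSeq-like preset is flat at
  0.05–0.15%. These are plausibility presets spanning the magnitudes of
  older and newer chemistry, not measurements of any instrument.
- **Reference sequence** is drawn per position from a seed and shared
  by all samples of an experiment; since error bins are keyed by
  substitution type, this is plumbing, not statistics.
- All randomness flows through explicit seeds; a fixed seed reproduces
  every table bit for bit, and the package restores the caller's RNG
  state.

## Numerical and evaluation choices

- Internal coordinates are 1-based inclusive throughout (matching
  GRanges/IRanges and the file dialects); points are genomic positions,
  not half-open intervals.
- The downsampling ladder (emulating 2–32-plex multiplexing) thins every
  count binomially with retention p = target/current mean column depth —
  equivalent in distribution to sampling reads — and *retrains* the
  calibration (error model, threshold, floor) at each level: a threshold
  selected at full depth reflects p-value magnitudes that thinned data
  cannot reach, so artifacts must always match the depth they are
  applied at.
- Performance metrics are averaged over ordered
  (calibration, tested) pool permutations, the way a multi-pool
  calibration experiment is properly evaluated; specificity counts all
  assayed non-truth bases in its denominator.
- Sensitivity denominators include truth variants lost to the coverage
  floor. Because the floor is the calibration sample's 5th depth
  percentile and the tested sample shares its coverage distribution,
  ~5% of tested bases fall below it *by construction* — a
  marginal-probability identity that no amount of between-sample
  coverage correlation removes. This bounds attainable sensitivity near
  95% and is the dominant false-negative source at high depth; at scale,
  the panel's own coverage heterogeneity determines which bases pay
  that 5%.

## Known limitations

- Substitutions only: gapped reads are excluded at pileup time, so
  indels are invisible by design.
- The error model conditions on direction, cycle and substitution type,
  not on base quality or sequence context beyond the local-window noise
  mask; systematic context effects absent from the calibration sample
  will not be modeled.
- At low depths the MCC threshold deliberately admits a handful of
  false positives to rescue true 1% variants (that is what maximizing
  MCC means there), and the strand-consistency filter can discard a
  direction holding contradicting zero-alt evidence; both effects cap
  the positive predictive value near 96–98% around 750× mean depth in
  the simulated experiments the test suite runs.
- The problem sizes used by the test suite and the acceptance script —
  150 amplicons (~36.6 kb), 200 truth SNPs, two to three pools,
  ~24,000× mean per-direction depth, five-level downsampling ladder —
  were chosen as the smallest experiment that exercises every stage at
  realistic operating points.
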