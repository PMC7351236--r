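---
title: "Models and methods behind meioscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meioscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meioscape)
```

meioscape implements two statistical tracks that are usually run together
when a mutation is suspected of redistributing meiotic crossovers and
perturbing DNA methylation: a recombination-landscape analysis of backcross
genotyping data, and a two-genotype comparison of whole-genome bisulfite
methylomes. This vignette records the models, the defaults and why they
were chosen, the numerical edge cases, and what the synthetic-data
generators do and do not emulate.

## The recombination model

A BC1 design crosses an F1 hybrid back to the recurrent parent, so each
progeny plant carries one recombinant gamete over a constant background.
At any SNP marker the genotype is either the recurrent homozygote (`A`) or
the heterozygote (`H`), and the calls along a chromosome switch state
exactly where the gamete's chromatid crossed over. Three estimators follow
from this readout:

* **Breakpoints.** A phase change between consecutive *informative*
  (non-missing) calls is one crossover, localised to the bracketing
  informative markers. Missing calls widen the bracket but cannot create
  or destroy a breakpoint. The breakpoint position used by all positional
  statistics is the bracket midpoint — the minimax choice when the true
  crossover is only known to lie inside the bracket.
* **Recombination fraction.** Per consecutive-marker interval,
  `r = (plants recombined in the interval) / (plants genotyped for the
  interval)`, where "recombined" means the two flanking calls are both
  non-missing and differ. This interval-local rule is deliberately
  independent of the breakpoint caller's widening rule: on heavily missing
  data the two can disagree, and surfacing that disagreement is more
  honest than hiding it behind a shared imputation.
* **Map distance.** Kosambi `d = 25 ln((1+2r)/(1-2r))` cM by default
  (moderate interference), Haldane `d = -50 ln(1-2r)` as the documented
  alternative. The Kosambi inverse is `r = tanh(d/50)/2`; the round-trip
  is tested to 1e-12. An interval with `r >= 0.5` is reported as-is with
  `cM = NA` and a flag — clamping would mask marker-order or genotyping
  problems.

**Interval comparison.** Two populations are compared interval by interval
with a two-sided Welch t-test on the per-plant 0/1 recombination
indicator. On binary data this is asymptotically the two-proportion z-test
(available via `method = "prop"`), but the t-form is well defined at any
sample size and degrades gracefully; intervals where both populations are
constant get `p = 1` when equal and `p = 0` when not, instead of a
division-by-zero failure. The family for multiple-testing correction is
all testable intervals across all chromosomes jointly; intervals with no
informative plants in either population are excluded *before* adjustment
and flagged.

**Two-stage FDR.** `bky_adjust()` implements the adaptive two-stage linear
step-up: Benjamini–Hochberg at `q' = q/(1+q)`, null-count estimate
`m0 = m - r1` from the stage-1 rejections, then Benjamini–Hochberg at
`q' m/m0`. Degenerate branches (no stage-1 rejections → reject nothing;
`m0 = 0` → reject everything) are explicit. Calibration is tested by
simulation: under 1,000 independent uniform p-values the empirical FDR
over 200 replicates stays at the nominal 1%.

**Distality.** Interval midpoints are rescaled per chromosome arm. The
arm-relative distance from the telomere is `midpoint / arm_length` on the
North arm and `(L - midpoint) / arm_length` on the South arm
(`anchor = "telomere"`); `anchor = "centromere"` is its complement, 1 at
the telomere. A midpoint exactly on the centromere belongs to the North
arm (tie-break, documented here because nothing in the data decides it).
The gradient is fitted as `y = a e^{bx}` by `stats::nls` minimising the
residual sum of squares, initialised from a log-linear regression on the
positive responses; with the centromere anchor, a distally clustered
landscape yields `b > 0`. If the start values already interpolate the data
(zero residual) they are accepted directly, since `nls` cannot iterate on
a perfect fit; an all-zero response is flagged degenerate with `r² = 0`
rather than fitted. `r² = 1 - SS_res/SS_tot` is reported even though the
model is nonlinear, matching common practice for these plots.

**Inter-crossover distances.** Chromatids with exactly two called
crossovers contribute `|mid2 - mid1| / L`. The null is the distance
between two independent uniform positions — mean exactly 1/3 — simulated
with the run's RNG, and compared by a two-sided Welch t-test plus a
Kolmogorov–Smirnov statistic for shape. Interference pushes the observed
mean above 1/3; distal clustering makes it bimodal (short pairs within one
chromosome end, or one pair split across both ends).

## The BC1 simulator

`simulate_bc1_population()` draws chromatids from a positional intensity
λ(x) on the relative coordinate:

* `uniform` — the wild-type-like baseline;
* `distal_exponential(rate b)` — `exp(b·d)` with `d` the per-arm relative
  distance from the centromere, so intensity rises `e^b`-fold towards both
  telomeres (default `b = 3`, giving the roughly 3-fold terminal
  enrichment seen in distally clustered maps);
* `piecewise` — an arbitrary non-negative table.

With interference shape ν = 1 the process is inhomogeneous Poisson: a
Poisson count with the configured per-chromosome mean, positions by
inverse-CDF sampling of λ. With ν > 1, events of a stationary
gamma-renewal process (shape ν, twice the chromatid rate, burn-in of 12
mean inter-arrivals) are thinned by 1/2 — chromatid sampling from a
bivalent-level process — and mapped through λ's inverse CDF. This
chromatid-level approximation sidesteps four-strand bookkeeping while
keeping the two consequences that matter here: the mean count per
chromatid equals the configured expectation, and double crossovers are
spaced more evenly than random. The obligate-crossover option rejection-
samples zero-event chromatids, the simplest law that preserves λ's shape.

Defaults mirror a typical *Arabidopsis* male-meiosis experiment: five
chromosomes with TAIR10-like lengths and centromeres, 96 markers allocated
by physical length and evenly spaced per chromosome, 5.1 expected
crossovers per gamete split across chromosomes by length, genotyping error
0 (fluorescence-based SNP genotyping with manual curation has a
call-error rate far below anything that would register here; the
parameter exists and is tested at non-zero values) and missingness 2%.
Starting phase is Bernoulli(1/2) per chromatid, so the heterozygote
frequency at every marker is 1/2 — a tested invariant.

One consequence deserves emphasis: **an even number of crossovers inside a
single marker interval is invisible** to any caller. At 96 markers and
~5 crossovers per gamete this deflates observed counts by roughly 5%, and
more under distal clustering (crossovers crowd into terminal intervals).
Recovery tests therefore compare the estimated mean and its 95% t-interval
against the *observable* truth — the number of marker intervals holding an
odd number of true crossovers — which is the quantity the marker design
can measure; the raw event mean is reported alongside. The acceptance
script's study conditions add interference ν = 5 for both genotypes,
since class I crossovers interfere in both; ν is otherwise a free
simulation parameter, not an estimate from any dataset.

## The methylome model

Cytosine contexts are read off the genome: a C is CG if the next base
(5'→3' on its own strand) is G, else CHG if the base after is G, else CHH.
Cytosines whose three-base window crosses a chromosome end or contains an
N are dropped and counted. Both strands are annotated; CG pairs are *not*
strand-collapsed by default (matching the CX report convention of listing
both strands), with `merge_cg_strands()` available to sum complementary
pairs.

All averaged quantities are **weighted levels** — Σ methylated / Σ total
over the pooled counts — not means of per-site ratios, so deeply covered
sites carry proportionally more information and tile levels conserve
genome-wide counts exactly (a tested invariant). A `level_type =
"site_mean"` flag provides the unweighted alternative. Coverage filtering
(≥ 5 reads) precedes everything.

Metagene profiles use fixed 100-bp flank bins over 1 kb on each side
(strand-oriented, upstream = 5') and, because feature lengths vary, a
fixed count of proportional body slices (default 20) rather than literal
100-bp body bins; `body_mode = "fixed_bp"` selects the literal reading,
with body windows counted from the 5' end. Features shorter than the bin
count contribute flanks only and are logged.

**Per-site testing.** Replicates are pooled within genotype and each
common site is tested with a two-sided Fisher exact test on the 2×2
methylated/unmethylated × genotype table. This replaces the smoothed
dispersion-shrinkage Wald test that dedicated bisulfite callers use:
pooling ignores between-replicate dispersion, so per-site p-values are
anticonservative when replicates truly disagree, and no smoothing means
single noisy sites are not rescued by their neighbours. The simulator
draws replicates exchangeably, so within the package's own validation
loop the Fisher test is exactly calibrated; on real data the DMR rule
chain below, not the raw site p-values, is the unit of interpretation.
The implementation enumerates the hypergeometric support vectorised
across sites (several hundred thousand tests per second) and is verified
against `stats::fisher.test` and a hand-written enumeration oracle for
all margins ≤ 30.

**DMR rule chain.** Candidate segments grow greedily left-to-right: a
segment opens at a significant site (`p < 1e-4`), absorbs subsequent
significant sites of the same difference sign as long as the significant
fraction over the spanned run stays above 1/2, and closes otherwise.
Candidates must span > 50 bp and contain ≥ 3 significant loci ("more
than 3" is read as the caller-standard ≥ 3; `min_dml = 4` gives the
literal reading). Surviving same-direction candidates closer than 50 bp
merge and are re-scored over all spanned sites; finally the pooled
weighted difference must reach the per-context cutoff (10% CHH, 20% CHG,
30% CG), and its sign sets hyper/hypo. The greedy segmentation with
tie-breaking toward longer runs is deterministic by construction —
determinism and documentation were prioritised over reproducing any
particular caller's unpublished segmentation. Relaxing a threshold can
only add candidates, which the tests exercise on fixed inputs; note that
because merging happens *between* the length/count filters and the effect
filter (the order the rule chain states), an added candidate can in
principle bridge two regions into one, so monotonicity of the final count
is a strong empirical regularity rather than a theorem.

Coordinates are 1-based inclusive in every emitted text format (CX
reports, DMR TSV) with BED output 0-based half-open; internal arithmetic
is plain integer positions.

## The methylome simulator

`simulate_cytosine_reports()` emits a random single-chromosome genome
(default 1 Mb, GC 0.36), places non-overlapping genes and TEs by
stick-breaking (60 genes and 40 TEs of 1–3 kb and 0.5–3 kb), and assigns
every cytosine the level of its enclosing class and context. Defaults are
leaf-like: gene CG 0.20 (gene-body methylation) with non-CG near zero,
TE CG/CHG/CHH 0.80/0.40/0.15, near-zero intergenic background. The mutant
adds per-context deltas inside every TE — defaults CG +0.12, CHG +0.21,
CHH +0.06, i.e. relative increases of 15%, ~53% and 39% over the TE
bases — clamped to [0, 1] with saturation flagged in the truth record.
Coverage is Poisson (mean 30 per replicate), methylated counts Binomial,
three replicates per genotype, everything seeded. Planted truth intervals
are the full TE extents per context with a non-zero delta; recovery uses
≥ 1 bp overlap with matching context and direction.

What the generator does **not** emulate: read-level artefacts (no FASTQ,
no incomplete bisulfite conversion, no mapping bias), replicate batch
effects or overdispersion, TE family structure, CpG-island-like
composition, or chromosome-scale methylation gradients. Passing recovery
tests therefore demonstrate that the pipeline's logic is correct under
exchangeable binomial sampling — they do not certify performance on real
libraries, where the dispersion caveat above applies.

## Problem sizes in the validation suite

The test suite sizes its simulations for tight statistical bounds at
interactive runtimes: 50,000 chromatids for the Poisson and
Kolmogorov–Smirnov checks of the landscape sampler; 100 replicate
uniform-vs-distal experiments of 300 plants each for landscape recovery
(CI coverage of the observable truth in ≥ 94/100, correctly oriented
interval flags in ≥ 95/100); 20 seeded 1-Mb methylomes with planted CHH
+0.25 TEs (twice the CHH cutoff) at 30× for DMR precision/recall ≥ 0.9,
plus 5 null methylomes (≤ 1 DMR on average); 200 replicates of m = 1,000
p-values for FDR calibration; exhaustive 3^8 genotype patterns for the
breakpoint caller and all-margin enumeration ≤ 30 for Fisher.

## Known limitations

* Double crossovers within one marker interval are invisible (inherent to
  the 96-marker design); all counts are "observed breakpoints".
* No multipoint likelihood mapping, marker-order inference, or
  genotyping-error EM correction; `r` is the simple interval estimator.
* The per-site Fisher test ignores replicate dispersion (see above).
* Interference is simulated at chromatid level, not through four-strand
  bundles, and is a free parameter — the package estimates nothing about
  interference from data.
* `overlap_fraction()` is binary per interval (≥ 1 bp); it reports no
  base-pair-weighted overlap.
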