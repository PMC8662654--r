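---
title: "Models and methods behind evoreseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind evoreseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoreseq)
```

evoreseq analyses longitudinal whole-population sequencing of serially
passaged microbial populations. This vignette documents the models the
package implements, the parameters that matter, the numerical choices made
where the design was genuinely open, and what the simulator-based validation
does and does not establish about real data.

## From polymorphism calls to trajectories

The unit of input is one polymorphism observation at one timepoint in one
population, with strand-resolved read support. Three artefact filters are
applied before any inference:

* **Strand support.** A mutation must be supported by at least
  `min_per_strand = 3` reads on each strand. Strand-biased support at depth
  ~600 is a classic mapping-artefact signature. At the trajectory level the
  rule is applied at *mutation scope*: a mutation that qualifies at one or
  more sampled timepoints keeps its entire trajectory. The alternative —
  zeroing every individually under-supported timepoint — would punch holes
  into genuine low-frequency stretches of real trajectories and make
  consolidation order-dependent.
* **Dense windows.** A call is excluded when more than `max_neighbors = 2`
  other calls from the same population and day fall within ±15 bp. Clusters
  of co-called polymorphisms in a short window are the deterministic proxy
  this package uses for "high local sequence variation", which otherwise
  requires manual inspection of alignments; both the window and the count
  are configurable for sensitivity analysis. The rule is symmetric and
  order-independent (neighbour counts are taken on the input set, not
  recomputed as calls drop).
* **Ancestral subtraction and repeat masking.** Variants present in the
  ancestor (matched on position and alternate allele) and calls inside known
  misalignment intervals are removed. These two filters and the strand
  filter commute; dense-window exclusion depends on the surviving set and is
  therefore defined to run last.

Coordinates are 1-based inclusive throughout, indels are anchored at the
first changed base, and mutation identity is the (position, ref, alt)
triple — the same position with a different alternate allele is a distinct
mutation. In a trajectory table, a cell at a sampled day where the mutation
was not called is 0 ("below detection"), not missing.

## Genotype cohorts and Muller genealogies

In an asexual population, mutations on the same genetic background rise and
fall together, so cohorts can be recovered from trajectory similarity alone.
The distance between two mutations is the mean absolute frequency difference
over the days at which at least one of the pair exceeds the detection floor;
undetected-by-both days carry no information about co-residence and are
excluded. Clusters are the connected components of the graph linking pairs
with distance ≤ `cutoff` — exactly a single-linkage agglomeration cut at the
cutoff, chosen because it is order-invariant and keeps the cutoff parameter
interpretable on the frequency scale (0.1–0.2 is appropriate at depth ~600;
looser cutoffs merge more mutations per genotype). The probabilistic model
of dedicated lineage-inference tools is deliberately not reproduced; the
cutoff-on-mean-|Δf| scale keeps published settings meaningful as knobs.

Genealogy inference uses the two Muller constraints: a derived genotype can
never exceed its background, `f_parent(t) ≥ f_child(t)`, and a genotype's
direct children cannot jointly exceed it, `Σ f_child(t) ≤ f_parent(t)`.
Genotypes are placed in order of first detection (ties: descending maximum
frequency), each attached to the placed candidate that satisfies both
constraints within `nest_tolerance` while minimising the summed
parent-child area — the tightest plausible background. `nest_tolerance`
defaults to 0.05: binomial sampling at depth ~600 gives a frequency SE of
at most ~0.02, and cohort means of a few members need headroom beyond one
SE.

Two error semantics are provided. By default (`strict = TRUE`) an
unplaceable genotype (no valid parent, and adding it as a root would push
the summed root frequencies past 1 + tolerance) is an error, as is a Muller
table whose clamping removes more than the tolerance at any day. In
`run_pipeline()` the non-strict variants are used: the genotype is attached
wherever the total constraint violation is smallest, and Muller tables are
renormalised, in both cases with a warning. On realistic noisy data many
individually tolerable violations can add up, and a pipeline that dies on
the worst population of a six-population experiment is less useful than one
that reports the inconsistency and continues.

**Fixation** is declared at the first sampled day a genotype reaches
`fixed_threshold = 0.97`, provided it never drops below threshold −
tolerance afterwards. The threshold is below 1.0 because sampled
frequencies rarely hit 1.0 exactly at finite depth. Persistence is
evaluated from the *first* crossing, and a genotype that collapses after
crossing is never counted as fixed — a transient excursion to high
frequency followed by collapse is the signature of a failed sweep, not of
fixation, even if the genotype later recovers. Each event sweeps the
genotype's own member mutations plus all not-yet-swept ancestral members,
so nested sequential sweeps partition the swept mutations without double
counting.

Genotype trajectories are unweighted member means: depths are near-uniform
across mutations, and depth weighting would couple the genealogy to the
sequencing run layout for no measurable gain.

## Gene-level parallelism

Independent mutations repeatedly hitting the same locus are the clearest
signature of selection. For a locus of length L bp carrying k of the M
total mutations on a G bp genome, the package tests enrichment with a
one-sided Fisher exact test on the 2×2 table of bases
(mutated/unmutated × inside/outside the locus), which is exactly the
hypergeometric upper tail P(X ≥ k) with population G, M successes and L
draws. This table orientation is a design choice — the natural "scatter M
point mutations uniformly over the genome" null — and makes the test
auditable against direct tail summation (the test suite holds agreement to
10⁻⁹ relative error). Multiple hits at the same site in different
populations count as independent cases.

Loci observed mutated ≥ 2 times form the screening set; the
Benjamini–Hochberg step-up at FDR Q = 0.05 is applied with m equal to the
number of loci actually tested. One caveat is worth stating explicitly:
conditioning the test set on k ≥ 2 is itself a selection step, and under a
uniform null nearly every *screened* locus has a small p-value (multi-hit
loci are rare events when the expected per-locus count is ~0.1). The
quantity that stays controlled under the null is the flagged fraction of
all loci in the genome, which the test suite verifies at genome scale
(6.5 Mb, 624 mutations, 1 kb loci); flagged fractions conditional on
screening should not be read as an FDR.

The neutral NS/S expectation is enumerated from a user-supplied codon-usage
table: each of the nine single-base changes of every codon is classified
against the standard genetic code, weighted by usage; changes that alter
the encoded product, including changes to or from a stop codon, count as
nonsynonymous (nonsense mutations are part of the NS class throughout the
package). Mixtures combine NS and S *weights*, not per-codon ratios.
Observed NS/S ratios are standardised by this expectation (default 2.96, a
typical value for a GC-rich bacterial genome under a uniform substitution
spectrum); a ratio of 1 means neutrality. With zero synonymous counts the
ratio is reported as `NA` — undefined, not infinite.

## Diversity and environment enrichment

Alpha diversity treats the detected mutation frequencies at one day as
abundances, normalised to proportions within the day — the only
self-consistent reading when frequencies of non-independent mutations are
fed to community-ecology indices. Shannon (nats), Gini-Simpson and inverse
Simpson are all emitted; they are distinct functionals and no attempt is
made to pick one as "the" diversity.

Group comparisons use the pooled-variance Student's t-test
(df = n₁ + n₂ − 2), the form appropriate for small balanced designs of
three populations per treatment (df = 4). The degenerate zero-variance
case reports t = ±Inf, p = 0 rather than erroring.

Environment-specific selection is read off paired re-sequencing of the
same population after biofilm-arm and planktonic-arm selection: ordinary
least squares of biofilm frequency (response) on planktonic frequency
(predictor), Cook's distance per mutation, and a flag when
D ≥ 4 × mean(D). The regression orientation is a package choice — the
direction label (biofilm-enriched above the fitted line, planktonic below)
comes from the residual sign, and flipping the orientation relabels but
does not materially re-rank influence. Only mutations detected in both
arms enter the fit. Points on an exact line are defined to have zero
influence (the ratio 0/0 is resolved to 0). Cook's distances are computed
via the standard linear-model machinery and validated against
leave-one-out refits to 10⁻⁸ relative error.

## Fitness, growth and mutation rates

* **Selective rate constant:** r = [ln(E₁/E₀) − ln(A₁/A₀)] / 2. The
  divisor 2 is kept as the published convention for one-day competitions
  and exposed as a parameter; values are therefore comparable with
  literature r values in the 2–10 range. Replicates where either
  competitor was undetectable yield `NA` — an invalid replicate to omit,
  never a zero to propagate.
* **Maximum growth rate:** the steepest least-squares slope of ln OD₆₀₀
  over sliding windows of 4 consecutive readings (~30 min at 10-minute
  sampling; the window is configurable). Windows containing non-positive
  OD are skipped rather than poisoning the log.
* **Fluctuation analysis:** the Ma–Sandri–Sarkar recursion
  p₀ = e^(−m), p_r = (m/r) Σ p_i/(r−i+1) gives the Luria–Delbrück
  mutant-count distribution under the Lea–Coulson model, and m is
  estimated by maximising the resulting likelihood on the log(m) scale
  (golden-section, relative tolerance ~10⁻⁶). Counts above `r_cap = 1000`
  are treated as right-censored with the distribution's upper tail —
  jackpot cultures carry little information about m beyond "large", and
  the O(r²) recursion must stay tractable. No plating-efficiency or
  post-plating growth corrections are applied. The distribution's 1/r²
  tail means partial sums converge like m/r_max; tests assert that decay
  law rather than an unattainable absolute tail bound. Mutation rate is
  m/Nt and fold changes are ratios of rates; the companion simulator draws
  Poisson(m) mutation events with clone sizes from the size-biased
  P(size ≥ k) = 1/k tail (inverse-transform, capped at the culture census).

## The serial-passage simulator

The simulator exists to generate *ground-truthed* inputs, and its defaults
encode the study conditions of the six-population experiment it emulates:
1:100 daily dilutions (log₂100 ≈ 6.6 doublings/day), 90 transfers, sampling
at days 17/25/44/66/75/90 (biofilm) or 17/44/66/90 (planktonic), sequencing
depth normal(617.1, 142.3) truncated at one read, a 5% detection floor,
a 6,537,648 bp genome with infinite-sites unique positions, and mutator
multipliers of 116 or 16.

Within a day, growth is deterministic in expectation — genotype i is
reweighted by (1 + sᵢ)^g relative to mean fitness — and all stochasticity
lives in three places: Poisson mutation arrivals, the optional binomial
bead-propagule subsample (biofilm mode, `bead_fraction = 0.1`, a life-cycle
bottleneck with no spatial structure), and the multinomial transfer
bottleneck to `n_bottleneck` cells. Fitness is cumulative along a lineage
(a child genotype carries its parent's mutations, so neutral hitchhikers
ride their background), beneficial effects are exponential with mean
`dfe_mean_s = 0.05` per generation and arise in a fraction
`frac_beneficial = 0.1` of arrivals, all other mutations are strictly
neutral, and mutator alleles are themselves neutral but heritable,
multiplying the rate of the carrying lineage and its descendants.

Drift is modelled at the **bottleneck scale**: the effective population is
the `n_bottleneck` cells surviving transfer, mutations arrive at rate
mu × multiplier × frequency × n_bottleneck × g per genotype per day, and a
new genotype enters at frequency 1/n_bottleneck. A census-scale formulation
(arrivals per census division, entry at one cell in ~10⁷) was considered
and rejected: under a 1:100 dilution essentially no census-scale arrival
survives its first bottleneck, so a desk-scale run would track tens of
thousands of stillborn genotypes and observe none, defeating the purpose of
ground truth. The cost of this choice is that `mu` must be read as the
rate of *trackable* mutations in the effective population, not the genomic
mutation rate, and that the defaults (`n_bottleneck = 10⁵`, `mu = 5 × 10⁻⁷`,
giving ~30 tracked arrivals per 90-day run) are sensible placeholders for
sensitivity analysis, not calibrated estimates — the experiment's true
effective sizes are not published to that precision.

What the simulator deliberately omits: spatial structure within the
biofilm, per-cell agent-based growth, sequencing error beyond binomial
sampling (no base-calling error, no mapping artefacts), deleterious
mutations, and recombination. Consequently, recovery tests on simulated
data validate the *inference machinery* — that clustering, nesting,
fixation accounting and the estimators invert the generative model they
assume — and not robustness to alignment artefacts or ecology outside that
model. The bundled benchmark for genotype recovery
(`simulate_planted_cohorts()`) therefore plants a fixed five-cohort
genealogy (two clades, three nested descendants, pairwise mean separation
≥ 0.15) and adds only binomial depth noise (SD ≈ 0.02), the regime in
which the clustering cutoff of 0.1 is provably conservative.

## Problem sizes and determinism

Every stochastic operation takes an explicit seed, and seeded runs are
bit-reproducible; the pipeline writes a JSON manifest of parameters and
input checksums so reruns can be verified byte-identical. Validation sizes
were chosen to make Monte Carlo noise negligible relative to the asserted
tolerances while keeping a full validation run in minutes on one core:
2000 replicates for neutral drift properties (99% binomial CI half-width
~0.03 on a fixation probability), 600 replicate days for mutator rate
ratios (3 SE ≈ 17 on a ratio of 116), 10⁴ cultures for fluctuation-assay
parameter recovery (m̂ within ±5% of m = 2), and 25–100 replicate
30-culture assays for mutator fold-change recovery (geometric mean within
2× of 116, the realistic accuracy of fluctuation assays at that size).

## Known limitations

* The dense-window rule is a deterministic surrogate for manual alignment
  curation; on real breseq output the two will not agree call-for-call.
* Genealogy inference is greedy. Cohorts whose trajectories cross or whose
  parents are extinct at the child's first detection can be mis-nested;
  the planted-cohort benchmark bounds accuracy only within its noise
  model.
* The multiplicity screen's conditional FDR caveat above applies equally
  to published analyses using the same screen-then-test recipe.
* `mss_mle` assumes equal final census across cultures and 100% plating
  efficiency.
* Published population-scale quantities that depend on the study's raw
  reads or wet-lab counts (per-population NS/S means, realized fixation
  counts, competition r values, isogenic fold changes) are not
  reproducible from bundled data; the package computes them from
  user-supplied or simulated inputs instead.
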