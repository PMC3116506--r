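---
title: "Profiling pyrosequencing error with control-fragment reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling pyrosequencing error with control-fragment reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyroerr)
```

## The problem

Pyrosequencing reads the genome flow by flow: the length of a homopolymer
(a run of three or more identical bases) must be inferred from a light
intensity, so the platform's characteristic failures are single-base
insertions and deletions in and around such runs, and the error rate is
anything but spatially or positionally uniform. Spiked-in control DNA
fragments are sequenced in every run without any PCR step, so every
discordance between a control read and its known template is a sequencing
error. `pyroerr` rebuilds the whole analysis chain around that idea:

1. assign each read to its reference and align it with affine gap
   penalties (`call_errors()`),
2. classify every aligned position as `none`, `insertion`, `deletion`,
   `mismatch` or `ambiguous` (`classify_errors()`),
3. summarize accuracy and quality per reference and window
   (`summarize_errors()`, `position_profile()`),
4. model the per-position error probability per plate with a logistic
   regression on seven covariates and split each covariate's contribution
   into unique/rest/shared deviance parts (`fit_logistic()`,
   `decompose_all()`),
5. map error rates across the PicoTiterPlate (`spatial_map()`), and
6. compute how many reads a majority-vote consensus needs at a given
   per-position error rate (`min_coverage()`).

A simulator with a truth log (`simulate_reads()`) stands in for real
sequencing data, so every stage is testable offline.

## The calling model

Reads are quality-trimmed prefixes of their template, so alignment is
global on the read with a free reference 3' overhang. The score is
$\sum \text{match/mismatch} - \sum_{\text{gaps}} (o + e\,\ell)$ with gap
open $o = 1$ and extension $e = 10$ per base, the values retained by the
original penalty screen; match/mismatch default to $+2/-1$ and are exposed
in `align_params()` because the original substitution scores were never
optimized. Ties are broken deterministically: match/mismatch over
deletion over insertion, which pushes indels to the 3' end of a run —
consistent with reporting an insertion at the reference base preceding
the gap.

Two consequences of this scoring are worth knowing:

* an insertion and a deletion separated by $k \le 6$ matched bases
  *always* score better as $k+1$ substitution columns than as two gaps
  (cost $3m > 3k - 21$ holds even with zero lucky matches), and lucky or
  repetitive context extends that range past 10 bp. At a 1% per-base
  error rate roughly 2% of calls are such merges, inflating mismatch
  counts at the expense of indel counts;
* an indel within the last few bases of a read is cheaper to render as
  trailing substitutions (or, at the very last position, as an early
  read end), so terminal events can change type or vanish.

Both effects would apply equally to the original ClustalW-based analysis;
they are properties of the gap-heavy scoring, not of this implementation.
The acceptance suite therefore tests exact recovery only for
well-isolated events and budgets these merges in rate-recovery checks.

## Homopolymer coding

Positions are coded on the reference: `0` away from any run, `1` for the
first and last base of a run and up to two flanking bases on each side,
and the run length (capped at 6) for strictly interior bases. Code 2
cannot occur. Three decisions the original description leaves open are
fixed here: runs longer than six are coded 6 (saturation is the least
surprising extension of an enumerated 3-6 scale), interior codes beat an
adjacent run's flank zone, and flank zones are clipped at sequence ends.

## The seven covariates and the models

For the balanced table every error position contributes a row
(`error = 1`) and an equal number of error-free positions is drawn per
plate without replacement (`error = 0`); positions at which any error was
reported — insertion anchors included — are excluded from the error-free
pool, since letting them double as controls measurably attenuates the
fitted slopes. Covariates: `Position` (reference position / reference
length), `Seq.type` (reference id), `Homopolymer` (code), `Dist.region`
and `Dist.plate` (distances to empirical centroids — the true plate
geometry is unpublished, so centers are data-driven), `Seq.length` (read
length) and `Region`. Models are fit per plate and per error type by
maximum likelihood (IRLS, deviance tolerance `1e-8`, 100 iterations),
with dummy-coded factors; rows carrying a *different* error type are
excluded from a type's fit so the two response classes stay clean. Wald
statistics stand in for the per-coefficient t tests of this literature.

The deviance decomposition follows the printed formulas exactly:
`part_xi = (dev(sub) - dev(comp))/dev(comp)` and
`part_rest = (dev(solo) - dev(comp))/dev(comp)`, with
`shared = 1 - part_xi - part_rest`. Note the denominator: because it is
the *complete-model* deviance, the shared term also absorbs the baseline
unexplained deviance and is large by construction — orthogonal covariates
do **not** drive it to zero; what orthogonality gives instead is
additivity of the deviance reductions, and that is what the test suite
asserts. Both parts are non-negative by nesting; convergence round-off
below `1e-6` is clamped to zero and anything larger raises an internal
consistency error.

## What the simulator emulates (and what it does not)

Each covered reference position receives at most one event from a single
categorical draw with per-type probabilities
`plogis(qlogis(baseline) + beta_pos * pos/len + beta_hp[code] +
beta_y * y + region offset)`; a probability sum above one is a
configuration error, never clipped. Defaults encode the reported
structure: indels enriched in homopolymers, all types rising toward the
3' end (mismatch and ambiguous rates rise fastest), opposite y gradients
for insertions and deletions, 15 congruent vertical strip regions on a
unit plate. Baselines were back-calculated analytically (one pass, not
iterated against any test) so realized full-length rates land near the
published control-read profile: insertions ~0.5%, deletions ~0.35%,
mismatch/ambiguous ~0.1% each. The read-length model is a mixture: full
length with probability 0.25, otherwise a uniform trim between 300 bp
and the reference length, reproducing the documented decline in read
numbers beyond ~300 bases; the true trimming law is unpublished.

The simulator does not model flow cycles, carry-forward/incomplete
extension chemistry, or quality scores; spatial effects are smooth
logit-linear gradients rather than optics-driven hot spots. A green test
therefore establishes that the pipeline recovers the *stated* generative
structure, not that real plates look like this.

## Numerical and interface choices

* Coordinates are arbitrary continuous units; all distances are relative.
  Simulated coordinates are rounded to six decimals so FASTA metadata
  round-trips exactly.
* Call tables carry a fifth column `read_pos` because the "first 101
  sequenced positions" window is defined in read coordinates from the 5'
  end; evaluated positions in a window are
  `min(window, read length) + deletions inside the window`, so inserted
  bases count as evaluated positions.
* `q_1/2` is implemented as the median of per-read error rates; the
  source's "mode q_1/2" wording is internally inconsistent and q_1/2
  conventionally denotes a median.
* Confidence intervals are normal-approximation binomial intervals with
  the conventional 1.96 multiplier, reported in percent.
* Permutation correlation tests default to 999 permutations (no count is
  published) with `p = (1 + #{|r*| >= |r|})/(n_perm + 1)` and BH
  adjustment across the 21 pairs; categorical variables enter via
  numeric codes (the homopolymer code by its value, reference and region
  by level index).
* Sliding-window maps default to a window of 1/20 of the coordinate span,
  stride half the window, and 20 reads minimum support; all three were
  unpublished and are echoed in the result attributes. Anchors use
  half-open cells so `stride == window` tiles the plate exactly.
* The per-stage seeds of `run_pipeline()` are derived from the master
  seed by a stage-name hash, so stages can be re-run independently and
  reruns are byte-identical.

## Worked example

```{r example, eval = FALSE}
refs <- synthetic_control_refs()
sim <- simulate_reads(refs, sim_config(n_reads = 200, seed = 1))
calls <- call_errors(sim$reads, refs)
summarize_errors(calls, sim$reads, window = "full")
min_coverage(p = 0.10, alpha = 0.01) # 5 reads
```

## Known limitations

* The six bundled references are synthetic stand-ins that reproduce only
  the published lengths, GC range and homopolymer counts of the real
  control fragments, which cannot be redistributed.
* Attribution inside homopolymers is positionally ambiguous by nature;
  per-read counts per type are the reliable unit there.
* The logistic models are per-plate and contain no interaction terms;
  shared deviance is reported, not decomposed further.
* No consensus caller is included: the coverage module answers "how many
  reads would a majority vote need", not "call the consensus".
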