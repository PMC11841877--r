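---
title: "Person-centered activity-cognition profiling with self-organizing maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Person-centered activity-cognition profiling with self-organizing maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somprofiler)
```

## The problem and the method

Children's physical activity, fitness, motivation and social experience of
sport do not act on cognition in isolation; a person-centered analysis asks
which *combinations* of these attributes co-occur in the same children and
how the resulting profiles differ on cognitive outcomes. `somprofiler`
implements that analysis chain for a 15-variable battery spanning a physical
domain (daily moderate-to-vigorous physical activity, cardiorespiratory
fitness, actual motor competence, BMI percentile, self-reported activity), a
psychological domain (perceived motor competence, perceived physical
literacy, intrinsic and identified motivation, perceived competence,
physical self-concept) and a social domain (relatedness, school enjoyment,
social identity, task-involving climate).

The chain is:

1. **Accelerometry.** Vertical-axis counts collected at 15-s epochs are
   consolidated to 60-s periods; maximal runs of at least 20 consecutive
   zero-count minutes are treated as non-wear; wear minutes are classified by
   the counts-per-minute cut-points *sedentary* (<= 100), *light* (<= 2295)
   and *MVPA* (> 2295); a day is valid with at least 8 h (480 min, not
   necessarily contiguous) of wear, a participant with at least three valid
   weekdays and one valid weekend day; mean daily MVPA is averaged over
   valid days only.
2. **Self-organizing map.** The 15 z-scored variables train a SOM on a
   hexagonal, non-toroidal sheet. Both sequential and batch training are
   implemented with four neighborhood kernels (gaussian, bubble, cut
   gaussian, Epanechnikov) and two initializations (uniform within the data
   range; linear along the two leading principal axes).
3. **Ensemble selection.** The full configuration grid — `repeats` x
   {sequential, batch} x four kernels x {random, linear} — is trained with
   distinct derived seeds (base seed + run index). At the study scale
   (100 repeats) this is 1600 maps. Every run's quantization error (QE, mean
   distance of cases to their best-matching unit) and topographic error (TE,
   fraction of cases whose first and second best-matching units are not
   lattice neighbors) are traced, and the map minimizing the product QE x TE
   is selected. A zero TE makes the product uninformative, so ties are broken
   by lower QE, then run order.
4. **Codebook clustering.** k-means (k-means++ seeding, Lloyd iteration, 100
   restarts) is run on the *neuron weight vectors* — not the participants —
   for k = 2..10, and the k minimizing the Davies–Bouldin index
   `DB = (1/k) sum_i max_j (S_i + S_j) / M_ij` is chosen (ties go to the
   smaller k, keeping the number of profiles interpretable). Participants
   inherit the cluster of their best-matching unit.
5. **Statistics.** Kruskal–Wallis tests (tie-corrected, chi-square
   approximation) with the epsilon-squared effect size `eps^2 = H / (n - 1)`
   compare clusters on every input and cognitive variable; Dunn's rank-based
   pairwise z tests with a Bonferroni multiplier of `k(k-1)/2` within each
   variable resolve which clusters differ; a chi-square test of independence
   (no continuity correction) checks the gender x cluster association. A
   noncentral-F power utility reproduces the design's sample-size
   computation (f = 0.272, alpha = 0.05, power = 0.80, 4 groups -> N = 152).

## Map sizing

The lattice is sized from the data: the target unit count is
`m = ceiling(5 * sqrt(n))` and the side ratio follows the square root of the
ratio of the two leading covariance eigenvalues, giving
`width = round(sqrt(m / sqrt(lambda1/lambda2)))` and the smallest height with
`height * width >= m`. With n = 194 and an eigenvalue ratio near 4 — which
the 15 z-scored variables of the reference cohort produce — this yields the
12 x 6 layout of the reference analysis. The exact derivation of that layout
was never published; this rule is a calibrated reconstruction, and both
constants are arguments of `map_size()`.

## Training schedules

Published SOM analyses rarely print their schedules, so the defaults follow
long-standing SOM-toolbox conventions: a rough phase with the radius
decaying linearly from `max(height, width)/4` (floored at 1) to 1, then a
fine-tuning phase from 1 to 0.5; epoch counts of `10 m / n` (rough) and
`40 m / n` (fine), floored at 5; sequential learning rates decaying linearly
0.5 -> 0.05 (rough) and 0.05 -> 0.01 (fine). All are overridable per call. A
radius of exactly 0 degrades every kernel to a winner-only indicator, which
makes one batch epoch one Lloyd k-means step — the property the test suite
uses to validate batch training against an independent oracle.

Z-scoring the inputs before training is the package's choice, not a
published detail: the variables mix minutes/day, laps, percentiles and
Likert scores, and unscaled Euclidean distance would be dominated by the
largest scales (BMI percentile, MVPA). Component planes are reported back on
native scales by inverting the transform.

## The synthetic cohort generator

No participant data are distributed, so the generator reproduces the
*structure* the analysis expects: six latent profiles (Excellers n=29,
Notables n=43, Resilients n=29, Moderates n=35, Strugglers n=38, Socializers
n=20; 194 children) with the published per-cluster medians and interquartile
ranges for all fifteen input variables, the published per-cluster outcome
distributions (math fluency, Digit Span, Stroop times/responses), and
Bernoulli gender draws with per-profile girl fractions (0.31, 0.657, 0.605
and 0.65 for Resilients/Moderates/Strugglers/Socializers as reported — the
Strugglers figure is printed as the impossible "60.05%" and is read as
60.5% — 0.50 for the "balanced" Notables, and 0.19 for Excellers, chosen so
the cohort-level proportion matches the reported 48.96% girls).

Each variable is drawn from a truncated normal on its admissible interval
with `sigma = IQR / 1.349`. Because simple truncation shifts the median of
scores near a scale boundary (several Likert medians sit at the ceiling),
the pre-truncation mean is solved numerically so that the *truncated*
distribution's median equals the target; when the target lies on the bound
itself the center is capped at bound ± 8 sigma, leaving the realized median
just inside the scale. Variables are drawn independently within profile —
only medians and IQRs were published, so no within-cluster covariance can be
matched; between-profile separation carries all the dependence structure.
Likert scores are kept continuous by default (`snap_likert = FALSE`) because
several published medians (e.g. 3.48) do not sit on any instrument grid.

Consequences for interpretation: passing recovery tests on this generator
shows the pipeline can find well-separated, independent-within-cluster,
truncated-normal profiles of the published geometry. Real questionnaire data
have within-profile correlation, skew and discreteness the generator does
not emulate, so recovery rates here are an upper bound on what identical
settings would achieve on real cohorts.

Outcome variables that were never printed per cluster (academic achievement,
perceived math/language performance) use synthetic medians consistent with
the reported direction of effects; they are placeholders for exercising the
reporting code, not reconstructions.

The count-trace generator schedules intensity bouts and non-wear blocks
minute by minute: background minutes draw 1–80 counts (sedentary and never
zero, so scheduled non-wear blocks are the only qualifying zero runs), bout
minutes draw uniformly within ±15% of the bout target clamped to the
intensity band, and 15-s traces split each minute multinomially. This makes
the downstream classification of every scheduled minute exact by
construction, which is what the boundary tests require.

## Numerical choices and degenerate inputs

* Ties everywhere (winner search, k-means assignment, ensemble selection)
  break toward the lowest index / smallest k, making every stage
  deterministic under a seed.
* Kruskal–Wallis on constant data is defined as H = 0, p = 1 (the tie
  correction denominator vanishes).
* Davies–Bouldin errors out on coincident centroids, naming the pair;
  `choose_k()` skips such k values rather than failing the scan.
* Empty k-means clusters are re-seeded from the point farthest from its
  assigned centroid; empty SOM neurons still participate in codebook
  clustering (the clustering operates on weights, not hits).
* Rows with missing inputs are rejected at matrix construction, mirroring
  the exclusion of incomplete cases from the reference analysis.
* 15-s series with trailing partial minutes drop those epochs rather than
  zero-padding; non-wear runs are evaluated on each participant's
  concatenated minute stream, so a run may span a day boundary.
* The power search uses the unconstrained smallest N by default;
  `balanced = TRUE` restricts to multiples of k (the G*Power convention),
  which matters for f = 0.25 (179 vs 180) but not for the reference
  f = 0.272 (152 either way).

## Known limitations

* The chi-square approximation to the Kruskal–Wallis p-value is poor at very
  small samples: against a full-enumeration permutation oracle at n = 8 the
  deviation can reach ~0.1 in the mid-range of p (it is much tighter in the
  significant tail). The test suite documents this honestly; at the study's
  n = 194 the approximation is unproblematic.
* Ensemble selection with QE x TE can prefer slightly over-smoothed maps
  when TE is exactly 0 for many runs; the QE tie-break mitigates but does
  not remove this.
* The sizing rule, schedules and the Epanechnikov reading of the "ep"
  kernel are reconstructions of toolbox conventions, flagged as such above.

## Problem sizes used in the checks

The bundled tests and the acceptance script run, by design, at these sizes:
the full 1600-map ensemble once on a 194 x 15 synthetic cohort; cluster-
count recovery over 20 seeds with a reduced ensemble (5 repeats, 80 maps per
seed) and 100 k-means restarts per k in 2..10; generator calibration at
n = 2000 per profile; all property checks (Lloyd equivalence, Davies–Bouldin
brute force, permutation enumeration) on instances of at most 20 points.
```{r, eval = FALSE}
# a complete run at reduced ensemble scale
coh <- generate_cohort(reference_profiles(), seed = 1)
coh <- generate_outcomes(coh, seed = 1)
res <- run_pipeline(coh, spec = ensemble_spec(repeats = 5), seed = 1)
print(res)
res$solution$db_trace
res$report$input_tests
```
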