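---
title: "Quantifying antibody binding to fibrils from immunogold annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying antibody binding to fibrils from immunogold annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilgold)
```

## The measurement problem

Immunogold electron microscopy makes antibody binding countable: a primary
antibody binds its epitope on a fibril, a gold-nanoparticle-conjugated
secondary antibody binds the primary, and the gold particle shows up as an
electron-dense dot on the micrograph. Annotating each micrograph gives two
point sets — gold-particle centres, and fibrils as straight line segments
(start and end coordinates). The analysis question is geometric: which
particles report a binding event on which fibril, and how strongly does each
fibril type recruit the antibody?

`fibrilgold` answers this in three stages: a distance-threshold binding
classification, a per-fibril binding score, and a gated statistical
comparison of score distributions across samples.

## The binding model

A particle's centre cannot coincide with its epitope. At most, the centre
sits one particle radius $r$ plus one primary-plus-secondary antibody
complex length $a$ away from the fibril *surface*, which itself lies half a
fibril width $d/2$ from the annotated fibril *axis*. A particle is therefore
counted as bound to a fibril when the shortest distance between its centre
and the fibril segment satisfies

$$\mathrm{dist}(p, f) \;\le\; r + a + \tfrac{d}{2}.$$

The defaults are $r = 5$ nm and $d = 17$ nm (both measurable directly on
micrographs of 10 nm gold and negatively stained fibrils) and $a = 30$ nm
for an IgG primary–secondary stack, giving a threshold of 43.5 nm:

```{r}
params <- binding_params(r = 5, a = 30, d = 17)
binding_threshold(params)
```

Two conventions are worth stating explicitly. First, the *fibril width* $d$
enters the threshold halved; figures sometimes quote the half-dimension
(8.5 nm) directly as a "diameter", and the two usages are numerically
consistent but terminologically confusing — this package always means the
full width by `d`. Second, the threshold comparison is inclusive
(`<=`): equality is a measure-zero event, but a deterministic rule is
needed and this is the one the tests pin down.

The point-to-segment distance is the standard clamped-projection formula:
perpendicular distance where the orthogonal projection of the particle
falls within the segment, Euclidean distance to the nearer endpoint
otherwise. The endpoint case needs no separate code path — clamping the
projection parameter to $[0,1]$ produces it automatically.

## Assignment and the binding score

A particle within threshold distance of several fibrils must count only
once. `assign_particles()` assigns each bound particle to the fibril at
minimum distance; exact ties (again measure-zero) go to the fibril that
appears first in the annotation file, so results are deterministic and
independent of floating-point vagaries in sorting.

Fibrils differ in length, so raw bound counts are not comparable.
`score_fibrils()` divides each fibril's bound count by its length,
yielding the **binding score** in particles per nm — one observation per
fibril, the unit of all downstream statistics. Fibrils with zero bound
particles stay in the table with score 0; dropping them would bias every
comparison upward.

Crowded fibrils (closer together than an antibody-gold complex is long)
are sterically inaccessible and, worse, make assignments ambiguous.
Curated manual annotations normally exclude them already, so
`crowding_filter()` is off by default; when enabled (exhaustive or
synthetic annotations) it greedily retains fibrils in file order, dropping
any fibril whose segment-to-segment distance to an already-retained fibril
falls below `min_separation`. The natural setting is the binding threshold
itself.

## Statistical comparison

Score distributions are zero-inflated and right-skewed in weakly binding
samples, so the test family is chosen by the data. `compare_samples()`
implements a two-step gated procedure:

1. **Normality gate.** Shapiro–Wilk per sample at $\alpha = 0.05$ (applied
   per group, not to pooled residuals). All samples compatible with
   normality → parametric route; otherwise — including any sample with
   $n < 3$ or zero variance, which cannot be tested — non-parametric.
2. **Omnibus test.** One-way ANOVA (parametric) or tie-corrected
   Kruskal–Wallis $H$ (non-parametric). Post hoc comparisons run only when
   the omnibus $p < 0.05$; an explicit `force_posthoc` flag exists for
   exploration and marks its output as forced.
3. **Post hoc pairwise.** Tukey's HSD after ANOVA, or two-sided
   Mann–Whitney $U$ with Bonferroni correction after Kruskal–Wallis. With
   a designated reference sample only the $k-1$ pairs involving the
   reference are tested and the Bonferroni multiplier is $k-1$ instead of
   $k(k-1)/2$; on the parametric route reference mode uses pooled-variance
   $t$ tests with the same multiplier (Tukey is inherently all-pairs).
   Mann–Whitney uses exact enumeration for tie-free samples of $n \le 20$
   per group and the tie-corrected normal approximation otherwise.

Adjusted p-values map to the standard strict-boundary asterisk notation
(`***` < 0.001, `**` < 0.01, `*` < 0.05, `ns` otherwise).

All statistics are computed on complete data. The 1.5 × IQR rule used by
the violin plots removes points from the *drawing* only; the test suite
asserts that toggling it changes no reported number.

Known limitations, stated rather than hidden: homogeneity of variances is
not tested before ANOVA; fibrils are pooled across micrographs within a
sample and treated as independent observations (no micrograph-level random
effect); no effect sizes are reported. These mirror the analysis the
pipeline reproduces.

## The synthetic generator

Real annotated datasets are large and external; the package therefore
ships a seeded generator whose ground truth is known exactly, so every
pipeline stage is testable end to end. `generate_sample()` emulates the
statistical structure of an annotated micrograph field:

- straight-segment fibrils with uniform random centre and orientation,
  lengths from a normal distribution truncated below — defaults mean
  400 nm, sd 150 nm, floor 50 nm, the scale of fibril extents visible at
  high magnification (the floor exists because sub-50 nm segments are not
  realistically annotatable and because the score's $1/L$ becomes
  heavy-tailed as $L \to 0$);
- per fibril, Poisson($\lambda_\text{bound} \times$ length) planted bound
  particles, uniform along the axis, perpendicular offset uniform on
  $[0, \text{threshold}]$ on a random side — the least-informative offset
  law consistent with the binding definition, and the one that makes the
  expected score exact;
- Poisson(background density × area) uniform background particles;
- fibrils separated by at least `min_separation` (default twice the
  threshold, so no point can be within threshold of two fibrils and every
  assignment is unambiguous), with endpoints kept one threshold away from
  the field border so each fibril's full capture region lies inside the
  field.

Defaults for simulated experiments are 6 samples × 150 fibrils per sample
on 8000 × 8000 nm fields — the order of the study designs this pipeline
targets, and enough power to separate a ten-fold rate difference cleanly.

In this isolated-fibril regime the expected per-fibril score has a closed
form. A fibril of length $L$ captures background from a stadium of
half-width $t$ (area $2tL + \pi t^2$), so

$$E[\text{score}] = \lambda_\text{bound} + 2\rho t + \rho\pi t^2\,E[1/L],$$

with $\rho$ the background density and $t$ the threshold. The end-cap term
carries $E[1/L]$, evaluated by numerical integration over the truncated
normal length law; substituting $1/E[L]$ would bias the term low (Jensen's
inequality) by an amount comparable to the Monte-Carlo bands the recovery
tests use.

```{r}
cfg <- synthetic_config(lambda_bound = 0.02, background_density = 1e-5)
expected_score(cfg, params)
```

The recovery tests run generate → assign → score over hundreds of seeded
replicates at several $(\lambda, \rho)$ settings and require the mean
score to sit within three Monte-Carlo standard errors of this expectation.

What passing these tests shows — and what it does not: the synthetic
fields validate the geometry, the assignment logic, the score arithmetic
and the statistical routing under a known ground truth. They do not model
stain texture, antibody kinetics, labelling efficiency, gold clustering,
or curved fibrils; agreement on synthetic data is a necessary, not a
sufficient, condition for trusting results on real micrographs.

## Numerical choices, collected

- All internal computation in nm; pixel inputs converted once at load.
- Threshold comparison inclusive; no rounding before comparison.
- Assignment ties → first fibril in file order.
- Shapiro–Wilk gate at $\alpha = 0.05$ per sample; $n < 3$ or zero
  variance forces the non-parametric route.
- Bonferroni: $\min(1, m \cdot p)$, monotone and capped; Tukey adjusted
  p clamped to at least the raw pairwise p.
- Violin KDE uses Silverman's rule-of-thumb bandwidth, recorded per sample
  in the figure's JSON sidecar along with the excluded-point counts;
  violins are clipped at 0 because scores cannot be negative.
- Run manifests record parameters, package version and input MD5 hashes,
  and deliberately no timestamps: repeated runs with identical inputs and
  seeds must produce byte-identical outputs.

## Problem sizes used by the test suite

The suite exercises the oracle-equivalence property on 100 random
instances (≤ 50 particles × ≤ 8 fibrils), score recovery on 3 settings ×
200 replicates of 12-fibril fields, the six-sample reference comparison on
100 seeds of the full 150-fibril design, and omnibus size calibration on
500 null replicates per route — sizes chosen to make Monte-Carlo bands
tight while keeping a full run around a minute on one CPU.
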