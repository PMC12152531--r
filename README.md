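# fibrilgold

Quantitative co-localization analysis for immunogold electron microscopy
of amyloid fibrils.

In immunogold EM, a primary antibody binds its epitope on a fibril and a
gold-conjugated secondary antibody renders the binding site visible as an
electron-dense particle. Micrograph annotation yields gold-particle centre
coordinates and fibrils as line segments. `fibrilgold` turns those
annotations into binding measurements and sample comparisons — for
structural biologists and neurodegeneration labs asking which fibril
polymorphs an antibody actually engages (for example, why an anti-amyloid-β
antibody decorates fibril folds with flexible N-termini but not folds whose
N-termini are buried in the core).

## The model

A particle at centre $p$ is **bound** to fibril $f$ when

$$\mathrm{dist}(p, f) \le r + a + \tfrac{d}{2}$$

where $\mathrm{dist}$ is the point-to-segment distance, $r$ the gold
particle radius, $a$ the primary+secondary antibody complex length, and
$d$ the fibril width. With the defaults $r = 5$ nm, $a = 30$ nm,
$d = 17$ nm the threshold is **43.5 nm** (≈ 44 nm). A particle within
threshold of several fibrils is assigned to the closest one only. Each
fibril's **binding score** is its bound-particle count divided by its
length (particles/nm) — one observation per fibril.

Score distributions are compared with a two-step gated procedure:
Shapiro–Wilk per sample routes to one-way ANOVA + Tukey HSD (parametric)
or Kruskal–Wallis + Mann–Whitney U with Bonferroni correction
(non-parametric); post hoc tests run only when the omnibus p < 0.05, and a
reference-group mode restricts them to the k−1 comparisons against the
reference. Statistics always use complete data; the 1.5 × IQR outlier rule
affects plots only.

A seeded synthetic-annotation generator (`generate_sample()`) plants bound
particles along fibrils at a known rate over a uniform background, with a
closed-form expected score (`expected_score()`), so the whole pipeline is
testable without any microscope data.

## Worked example

Simulate three samples — two strong binders and a weak reference — then
score and compare them:

```r
library(fibrilgold)

params <- binding_params(r = 5, a = 30, d = 17)
binding_threshold(params)
#> [1] 43.5

lambdas <- c(`type-I` = 0.02, `type-II` = 0.018, `weak-ref` = 0.002)
samples <- lapply(seq_along(lambdas), function(j) {
  cfg <- synthetic_config(n_fibrils = 150, lambda_bound = lambdas[j],
                          background_density = 1e-5, seed = 40 + j)
  sim <- generate_sample(cfg, params, sample_label = names(lambdas)[j])
  score_fibrils(assign_particles(sim$annotations, params),
                sim$annotations)$score
})
names(samples) <- names(lambdas)

round(sapply(samples, mean), 4)
#>   type-I  type-II weak-ref
#>   0.0213   0.0185   0.0033

compare_samples(samples, reference = "weak-ref")
#> Binding-score comparison (nonparametric route)
#>   groups: type-I (n=150), type-II (n=150), weak-ref (n=150)
#>   omnibus Kruskal-Wallis H: statistic = 272.8, p = 5.66e-60
#>   post hoc (m = 2 comparisons):
#>  label_a  label_b    raw_p adjusted_p stars
#>   type-I weak-ref 1.02e-47   2.04e-47   ***
#>  type-II weak-ref 4.86e-44   9.72e-44   ***
```

The mean scores recover the planted rates (0.02, 0.018, 0.002 /nm, each
plus ~0.001 /nm of background capture), and both strong binders differ
from the weak reference at `***` (adjusted p < 0.001).

Real annotations enter through `read_annotations()` (CSV in nm or pixels,
optional axis swap for (row, col)-ordered exports); `violin_plot()` and
`overlay_plot()` reproduce the standard figure styles. A command-line
front-end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "fibrilgold.R", package = "fibrilgold"))') \
    simulate --out-dir sim --seed 1
```

See `vignette("immunogold-colocalization")` for the model's assumptions,
the generator's design and the package's numerical choices.

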