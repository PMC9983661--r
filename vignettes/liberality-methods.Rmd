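---
title: "Transcriptome entropy as a dedifferentiation index: models and methods"
author: "liberality package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome entropy as a dedifferentiation index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liberality)
```

## The measurement model

A differentiated tissue devotes most of its transcriptional output to a
small set of genes; in primary culture the tissue loses that focus and
the expression distribution flattens. The package operationalizes this
as the Shannon entropy of the per-sample gene *occupation rates*
`p_i = c_i / N` (counts over library size):

$$H \;=\; -\sum_{p_i > 0} p_i \log_2 p_i .$$

`H` rises with dedifferentiation and falls with (re)differentiation, so
it is reported as a biological quantity in its own right — *liberality*
— rather than as a generic alpha-diversity statistic. Base 2 (bits) is
the default; nats are available via the `base` argument, and every
comparison the package makes is base-consistent. Two conventions matter:

* `0 · log 0 = 0`, and no pseudocounts are added. Pseudocounts would
  break the scale invariance `H(c · counts) = H(counts)`, which is what
  lets raw and depth-normalized counts give identical entropies.
* Entropy is computed over each sample's *observed* genes; the
  annotated total `G_total` is carried in the output for reporting
  only, since zero-count genes contribute nothing either way.

Derived indices: evenness `H / log2(m)` (in [0, 1] for the plug-in
estimator, `m` = observed genes) and the effective gene number `2^H`,
the count of equally-expressed genes with the same entropy — a more
interpretable scale than bits when comparing samples.

Counts are accepted as non-integer weights because upstream quantifiers
often emit estimated counts; nothing downstream assumes integrality.
Gene-length (TPM-style) normalization is deliberately *not* applied by
default — the occupation rate is a property of the mapped read mass —
but a per-gene weight vector can be supplied to `diversityTable()` when
a length-corrected variant is wanted.

### Estimator bias

The plug-in estimator is negatively biased at finite `N` (sampling
zeros truncate the tail). The optional Miller–Madow correction adds
`(m − 1)/(2 N \ln 2)` bits. On multinomial draws from a known profile
(50 genes, 500 reads, 2000 replicates — see the test suite) the
correction reduces the mean absolute bias by roughly a quarter. For the
deep libraries the pipeline targets (`N ≥ 10^5`) the bias is a few
millibits and, being nearly constant across samples of similar depth
and richness, barely perturbs slope estimates; the plug-in estimator is
therefore the default.

## The inferential step

The scientific question — does extract dose (or culture time) shift
entropy? — is answered by simple linear regression of per-sample
entropy on the covariate with a two-sided t-test on the slope,
implemented from first principles in `fitSlope()`:

$$\hat\beta = S_{xy}/S_{xx}, \quad
  \mathrm{se}(\hat\beta) = \sqrt{\frac{SSE}{(n-2)\,S_{xx}}}, \quad
  t = \hat\beta/\mathrm{se}(\hat\beta),$$

with the two-sided p-value from the regularized incomplete beta form
$p = I_{\nu/(\nu+t^2)}(\nu/2, 1/2)$, `ν = n − 2` (for `ν = 1` the
exact Cauchy form `1 − 2 arctan|t|/π` is used; the two are analytically
identical). The test suite cross-checks both halves against independent
oracles: a refining dense grid search over (mean level, slope) for the
least-squares fit, and numerical integration of the t density for the
tail probability (agreement to 1e−8 for 1–30 degrees of freedom).

Design choices, each genuinely open:

* **Covariate encoding.** Dose enters as the decimal dilution fraction
  exactly as recorded (1/100 → 0.01, control → 0). A log encoding is a
  reasonable alternative but a pure log scale is precluded by the
  zero-dose controls, so `entropyTrendTest(encoding = "log10")` uses
  `log10(dose + d0)` with a configurable offset (default: smallest
  positive dose / 10). The linear-fraction encoding is the default
  because the synthetic generator defines its truth on that scale,
  making effect sizes directly recoverable.
* **Two-sided test**, matching a neutral null ("dose does not affect
  entropy"), even though the expected biological effect is a decrease.
* **Per-strain contrasts.** Each strain is tested separately and
  midgut/cabbage treatment arms are excluded from dose regressions via
  the `strain`/`treatments` filters, mirroring the dose-design subsets
  (control + two dilutions × 3 replicates per strain).
* **No multiple-testing correction** across the handful of reported
  contrasts; raw p-values are reported and the caller can adjust.
* **Degenerate inputs.** A constant response gives `β̂ = 0, t = 0,
  p = 1`; an exact linear relation (`SSE = 0`, detected at relative
  1e−12) reports `p = 0` with a `perfect_fit_warning` rather than an
  exception, so simulation sweeps never abort; a constant covariate or
  `n < 3` raises a classed error.

## The synthetic-data generator

No public count matrix accompanies the motivating experiment at desk
scale, so the generator is a first-class module that emulates the
study's *structure*: about 14,000 annotated genes; a control plus
1/1000 and 1/100 extract dilutions with three replicates each (nine
samples per strain); skewed expression in differentiated tissue and a
flatter profile as dedifferentiation proceeds; entropy responding
linearly to dose with replicate noise; and an optional viral
contaminant block.

Mechanics: a Zipf base profile `q_i ∝ i^{−s}` is flattened through a
temperature parameter, `p_i ∝ q_i^{1/τ}` (computed in log space), whose
entropy is continuous and non-decreasing in `τ` — from
`log2(#maximal genes)` as `τ → 0` to `log2(m)` as `τ → ∞`. For each
sample a true entropy target `H0 + β·dose + ε`, `ε ~ N(0, σ²)`, is
drawn, `τ` is solved by bisection on `log τ` to 1e−6 bits, and `N`
reads are drawn from the resulting profile with `rmultinom()`. Targets
pushed outside the attainable range by noise are clipped *and flagged*
in the per-sample truth; a noiseless target outside the range is an
error before any sampling. A single RNG stream (Mersenne–Twister,
inversion normals) is consumed in a fixed per-sample order — noise
draw, then multinomial — so a configuration plus seed reproduces counts
bit-identically; per-sample substreams were rejected as needless
complexity at desk scale.

Default parameters, chosen once as a realistic rendering of the study
design: `genes = 14000`, `doses = c(0, 0.001, 0.01)`, `reps = 3`,
`libSize = 1e6` reads (a modest bulk mRNA library), `zipfExponent = 1`
(a generic rank-abundance skew; the true in vivo shape is unknown, so
the exponent is an exposed parameter rather than a constant),
`H0 = 10` bits (≈ 1000 effective genes of 14,000 — concentrated but
not degenerate), `doseEffect = −50` bits per unit dose (a 0.5-bit drop
at the 0.01 dose, comfortably detectable against), `noiseSd = 0.05`
bits of replicate-level variation, and no contaminant. The recovery
experiments in the tests use a scaled problem (2000 genes, 2×10^5
reads, noise 0.01 bits) so that 200 repeated pipeline runs complete in
tens of seconds; the vignette states these sizes as the package's
chosen simulation scale.

The contaminant option appends a disjoint block of `contam_`-prefixed
genes receiving a fixed fraction `c` of reads uniformly. Because the
block is disjoint and internally uniform, mixing it in can only raise
the true entropy (verified numerically in the tests) — which is why a
viral infection of a culture does not mask an entropy *decrease* driven
by the host profile, and why the reserved prefix exists: downstream
filtering (`rowData(se)$contaminant`) can be exercised end-to-end.

What the generator does **not** emulate: read-level error, gene-length
effects, overdispersion beyond multinomial sampling (no
negative-binomial layer), batch structure, or correlated replicate
deviations. Passing tests therefore demonstrate correctness of the
estimators and the inference under the stated sampling model, not
robustness to every property of real libraries.

## Quality control

`multihitQC()` implements the reference-acceptance check applied before
analysis: the fraction of ambiguously mapped reads,
`multi/(unique + multi)`, flagged when strictly above 30% — the
threshold at which a candidate reference transcript set is rejected.
The artifact consumes uniquely-mapped gene counts; multi-mapped reads
enter only through this rate, not as a per-gene allocation problem.

## Visualization

Occupancy bar charts stack each sample's occupation rates sorted
descending within the sample (whether the original figures sort
globally or per sample is not stated; per-sample descending is chosen
and documented here), shaded light-to-black by rank so the rare-gene
mass forms the dark region. Entropy scatter plots place one point per
sample at (covariate, H) with the OLS line overlaid. Both plots are
built from explicit render-data frames (`occupancyRenderData()`, the
ggplot `$data`), so tests assert numerical equality with the diversity
module instead of comparing pixels; images save as PNG or SVG.

## Numerical choices

* Entropy sums run over strictly positive rates only; profile validity
  requires `|Σp − 1| ≤ 1e−9`.
* Temperature bisection: 200 iterations max on `log τ ∈ [log 1e−4,
  log 1e6]`, tolerance 1e−6 bits; targets outside the entropies
  attainable on that interval raise a range error reporting the bounds.
* Tables are written with 15 significant digits so read/write
  round-trips are the identity up to float formatting.
* The perfect-fit detection threshold is `SSE ≤ 1e−12 · S_yy`.

## Known limitations

* Absolute entropy values depend on the log base and on sequencing
  depth (via estimator bias); only within-base, similar-depth
  comparisons are meaningful. The dose/time *slopes* are the robust
  quantity.
* The plug-in estimator's bias varies slightly with true entropy
  (through observed richness), which can nudge slope estimates at
  shallow depth; at the default depths this is orders of magnitude
  below the replicate noise.
* The linear model is a two-parameter description; saturating
  dose-response shapes are outside its scope, as are mixed models for
  nested designs.
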