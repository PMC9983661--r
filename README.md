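# liberality

Quantifying cellular dedifferentiation from bulk RNA-seq as the Shannon
entropy of the transcriptome.

## The problem and who this is for

Primary tissue cultures tend to lose their mature, specialized expression
state — they *dedifferentiate*. A differentiated tissue expresses a few
genes intensively, so its transcriptome is concentrated; a dedifferentiating
culture flattens that distribution. The information entropy of the
per-sample gene expression distribution therefore works as a direct,
scalar index of (de)differentiation — here called **liberality**:
dedifferentiation is an entropy increase, (re)differentiation an entropy
decrease. The motivating application is silkworm (*Bombyx mori*) fat-body
primary cultures, where diet-derived media components (mulberry leaf
extract) are tested for their ability to re-differentiate the tissue, but
the machinery applies to any gene-level count matrix with per-sample
covariates.

The package is aimed at bioinformaticians analysing such experiments: it
takes a genes × samples count matrix plus a sample sheet and answers
"does this covariate (extract dose, culture time) shift transcriptome
entropy, and by how much?"

## The model

For a sample with counts `c_i` over genes `i = 1..G`, the **occupation
rate** of gene `i` is `p_i = c_i / Σ_j c_j`, and the transcriptome
entropy (in bits) is the plug-in estimate

    H = − Σ_{p_i > 0} p_i · log2(p_i)

with derived indices: evenness `H / log2(m)` (`m` = observed genes) and
the effective gene number `2^H`. An optional Miller–Madow correction
`H + (m − 1)/(2 N ln 2)` counteracts the estimator's negative bias at
finite library size `N`.

The inferential step is an ordinary least-squares fit of per-sample
entropy against a covariate `x` (dose as a decimal dilution fraction, or
culture hours), `H = α + β·x + ε`, with the two-sided t-test of
`β = 0`: `t = β̂/se(β̂)`, `p = I_{df/(df+t²)}(df/2, 1/2)` on
`df = n − 2`. The regression and the t tail probability are implemented
from first principles (centred sums; regularized incomplete beta) and
are cross-checked against independent oracles in the test suite.

A seeded generator produces synthetic experiments with the structure the
analysis assumes: a Zipf rank-abundance base profile flattened through a
temperature parameter (`p_i ∝ q_i^{1/τ}`) so each sample attains a
prescribed true entropy `H0 + β·dose + noise`, then multinomial read
sampling, optionally with a disjoint uniform contaminant gene block
(viral transcripts in an infected culture).

## Worked example

```r
library(liberality)

cfg <- SimulationConfig(genes = 2000, libSize = 200000,
                        baselineEntropy = 9, seed = 42)
se  <- simulateExperiment(cfg)          # SummarizedExperiment, 9 samples
div <- diversityTable(se)
head(div, 4)
#>   sample_id H_bits estimator G_total    m     N evenness effective_genes
#> 1       S01  9.055    plugin    2000 2000 2e+05   0.8258           532.0
#> 2       S02  9.074    plugin    2000 2000 2e+05   0.8274           538.8
#> 3       S03  8.959    plugin    2000 2000 2e+05   0.8170           497.8
#> 4       S04  8.997    plugin    2000 2000 2e+05   0.8205           511.0

st <- entropyTrendTest(div, simulatedSampleSheet(se), covariate = "dose",
                       strain = "p50", treatments = c("control", "mulberry"))
st
#> Entropy trend test (OLS slope, two-sided t)
#>   contrast: H_bits ~ dose [p50; control/mulberry], n=9
#>   n = 9, covariate encoding = fraction
#>   slope = -46.9167 bits/unit (se = 3.28824), intercept = 9.01266 bits
#>   t = -14.268 on 7 df, p = 1.97486e-06
```

The control samples sit near the 9-bit baseline (about 500 effective
genes out of 2000); entropy falls by roughly 0.5 bits at the strongest
dose (dilution fraction 0.01), and the fitted slope of −46.9 bits per
unit dose recovers the generator's true effect of −50 (its 95% CI,
`confint(st)`, is [−54.7, −39.1]). The small p-value rejects the null
that dose does not affect transcriptome entropy.

The same flow runs from a shell:

```sh
Rscript inst/scripts/liberality.R simulate --genes 2000 --libsize 100000 \
    --doses 0,0.001,0.01 --reps 3 --beta -50 --h0 9 --seed 7 --out out/
Rscript inst/scripts/liberality.R entropy --counts out/sim_counts.tsv --out out/div.tsv
Rscript inst/scripts/liberality.R test --diversity out/div.tsv \
    --sheet out/sim_samples.csv --covariate dose --out out/slope.tsv
Rscript inst/scripts/liberality.R plot --kind entropy_scatter \
    --diversity out/div.tsv --sheet out/sim_samples.csv --out out/scatter.svg
```

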