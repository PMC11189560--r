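---
title: "Models and design choices in adaptscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in adaptscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptscan)
```

adaptscan analyzes replicated two-environment experimental evolution in
outcrossing plants: did allele frequencies change more than drift allows,
are the changes soil-specific (antagonistic pleiotropy vs conditional
neutrality), and do the evolved lines phenotypically outperform foreign
lines in their own soil? This vignette explains each model, why its
defaults are what they are, and what the package's synthetic validation
does and does not establish.

## The simulated experiment

`experiment_config()` encodes the factorial greenhouse design: two soils ×
herbivory (±) × pollination (bee/hand) = 8 treatments, each with two
isolated replicate lines of 49 plants. Generations 1 and 10 are sampled.
Between them lie **nine transmissions**: eight under selection and the
treatment's pollination regime, then one insect-free hand-pollinated
transmission. (The final two generations are grown without insects; only
the transmission *within* that wash-out phase is selection-free, because
the last selective generation reproduces under its own treatment to found
it. This bookkeeping is why the drift correction below uses t = 9.)

One transmission of one replicate (`select_and_mate()`) proceeds as:

1. **Adaptation score.** Each plant's log relative fecundity is
   `A = Σ_j g_j s_j(soil)`, with `g_j` the alt-allele dosage and
   `s_j(soil)` the locus's selection coefficient in the soil the line
   grows in.
2. **Visitation.** Under bee pollination only the k most attractive plants
   are visited (k = the treatment's effective population size, 21–28 seed
   parents, capped by the 35-visit pollen budget); attractiveness is the
   simulated flower phenotype, which includes the `fitness_coupling ×
   A` term — plants maladapted to their soil flower less and are visited
   less. Visited plants serve as mothers *and* as the pollen pool (bees
   move pollen between the plants they visit). Under hand pollination 28
   random mothers receive pollen from random donors.
3. **Fecundity.** Expected seed set of a visited mother is multiplied by
   `exp(A)`.
4. **Contributions.** Seed sets are converted to next-generation quotas by
   `contribution = seed_set / replicate_total × 49`; integer offspring
   counts use largest-remainder rounding, so quotas and counts both sum to
   exactly 49 every generation (asserted in the `audit` table of
   `run_experiment()`). A plant with zero seed set never reproduces, and
   an all-zero replicate raises an extinction error.
5. **Transmission.** Each offspring draws one gamete from its mother and
   one from a distinct father (self-incompatibility), independently per
   locus (free recombination).

**Why the coupling term exists.** With fecundity selection alone, strong
multi-locus selection makes `exp(A)` span orders of magnitude, a handful
of mothers monopolize the quota, and genome-wide drift collapses far below
the design's stated effective sizes. Routing most of the selection through
attractiveness ranking (a truncation-type selection with bounded intensity)
keeps realized drift consistent with Ne ≈ 21–28 while still producing
strong per-locus responses. It is also the biology of the system: the
flower count is the fitness proxy precisely because pollinator visitation
tracks it. Defaults: intercept 30 flowers, residual sd 6, soil main effect
−3 for the poorer soil, coupling 8 flowers per log-fecundity unit, and a
local-advantage term of 3 flowers (0.5 residual sd) for lines grown in
their native soil — the generator's built-in local-adaptation scenario.

**Locus panel.** `default_architecture()` places 20 antagonistic loci
(|s| = 0.5, opposite signs in the two soils, founder frequency 0.5 so both
directions have room), 8 + 8 conditionally neutral loci (selected in one
soil only), and 150 neutral loci whose founder frequencies follow the
U-shaped Beta(0.5, 0.5) spectrum of drifting variants, clipped to
[0.05, 0.95]. Loci sit 5 kb apart except for deliberate 500-bp pairs that
exercise window pruning. |s| = 0.5 is a *strong-selection validation
scenario* — chosen, via a prototype power analysis before the pipeline was
frozen, so that expected |Δp| (≈ 0.4) clears the classification thresholds
relative to drift noise (sd ≈ 0.18). It is not an estimate of the real
experiment's selection strengths.

## Allele-frequency change and the CMH test

Frequencies are computed from non-missing calls; change is
`Δp = p_gen10 − p_gen1`, signed on the alt allele (field practice does not
fix a polarization; every downstream rule is
polarization-symmetric, so the choice only relabels signs — verified by a
flip-invariance test). For each treatment the two replicates form the
strata of a Cochran–Mantel–Haenszel test on generation × allele counts:

$$X^2 = \frac{\left(\sum_k (a_k - E_k)\right)^2}{\sum_k V_k},$$

with hypergeometric mean/variance per stratum, no continuity correction
(this keeps allele-label invariance exact), chi-square with 1 df. In
**drift-aware** mode each $V_k$ gains the binomial drift variance of the
final-generation allele count over t Wright–Fisher transmissions at
effective size $N_e$:

$$V_k' = V_k + n_{10,k}^2\,\hat p_k(1-\hat p_k)\left[1 - (1 - 1/(2N_e))^{t}\right].$$

As $N_e \to \infty$ (accepted as `ne = Inf`) the classical statistic is
recovered exactly, and the drift-aware statistic never exceeds the
classical one.

**Power arithmetic, and when to use which mode.** At this design's scale
(49-diploid cohorts, $N_e \approx 25$, t = 9) the drift term dominates:
per stratum, sd ≈ 19 allele counts against a signal of ≈ 49·Δp, so even
Δp = 0.45 gives z ≈ 1.5. The drift-aware test is therefore a *calibration
instrument* — its type-I error on neutral Wright–Fisher panels is ≈ 0
(the acceptance suite verifies ≤ 0.075, and ≈ 0 discoveries after BH) —
but it cannot certify individual loci at n = 49. The classification
pipeline consequently runs the CMH in classical mode and controls drift
through the *replicate-consistency* requirement (same direction of change
in both independent replicates) plus the AP/CN magnitude thresholds,
which is also how the comparative logic of the original design controls
drift. Both modes are exposed; `cmh_options(drift_aware = TRUE)` remains
the default object.

Inference then applies, in order: window pruning (non-overlapping 2-kb
windows anchored at coordinate 1; lowest p wins, position breaks ties),
Benjamini–Hochberg across the window representatives within a treatment,
the q < 0.05 threshold, and replicate-direction consistency
(`significant_set()`).

## Ridge-regression BLUP marker effects

The fitness-proxy trait is regressed on all markers at once:
$y = \mu 1 + X g + e$, $g \sim N(0, \sigma_g^2 I)$,
$e \sim N(0, \sigma_e^2 I)$, with $X$ coded −1/0/+1 (0 = heterozygote),
markers with more than 50% missing data removed (exactly 50% is kept — the
rule is strict), missing entries imputed by the column mean, and the trait
Z-transformed within each treatment × replicate fit. Sixty percent of each
dataset trains the model. REML estimation profiles the restricted
likelihood in $\lambda = \sigma_e^2/\sigma_g^2$ through the spectral
decomposition of $K = XX'$ (one eigendecomposition, then 1-d optimization:
exact, deterministic, O(n³)); effects are the dual-form solution
$\hat g = X'(K + \lambda I)^{-1}(y - \hat\mu 1)$, which the test suite
checks against the primal $(X'X + \lambda I)^{-1}X'(y - \hat\mu 1)$ to
1e-8.

**Cross-replicate retention** keeps markers *present with a finite
estimate* in both replicate fits. Presence — not a nonzero point estimate
— is the criterion: a locus swept to fixation has a constant genotype
column and a structurally zero ridge effect, and discarding it would
remove precisely the strongest selection signals. (The alternative
"nonzero" reading was implemented first and measurably biased the
end-to-end recovery; the change is a deliberate design decision, made on
that mechanistic ground.)

**Recovery benchmark.** `simulate_blup_panel()` generates the kind of data
this estimator faces: 40 causal haplotype blocks each tagged by 5 markers
at 2% discordance (dense resequencing panels are locally redundant), a
polygenic trait at h² = 0.5, n = 150. With *unlinked* markers at these
dimensions the rank correlation between |estimated| and |true| effects is
mathematically capped near 0.27 (shrinkage leaves too little per-marker
information), which is why the benchmark models linkage; the suite
requires a median ≥ 0.4 over 20 panels.

## AP/CN classification

For each pollination × herbivory group, candidate markers must be retained
by both soils' replicate models and significant in at least one soil. The
rules, all inequalities strict, both replicates individually:

* **AP** — |Δp| > 0.1 in every replicate of both soils, consistent
  direction within each soil, opposite direction between soils, *and*
  significant in both soils.
* **CN** — |Δp| > 0.2 in both replicates of one soil (either direction),
  |Δp| < 0.1 in both replicates of the other, *and* significant in the
  large-change soil. (Requiring significance in both soils would
  contradict CN's definition — the small-change soil is by construction
  near-null — so the one-soil discard rule is applied only on the AP path;
  `strict_cn = TRUE` applies it to CN too.)
* **OTHER** — anything else.

AP and CN are mutually exclusive because the CN small-soil bound equals the
AP bound; the test suite proves the implementation equal to a brute-force
restatement of the rules over the full delta grid. Classified markers are
annotated with genes whose intervals intersect an inclusive ±1-kb flank.
Percentages are reported against the group's significant-marker count,
rounded half-up to one decimal. Prevalence of a pattern between two
treatments is compared with a binomial GLM (1-df deviance statistic),
with the 2×2 Pearson chi-square reported alongside.

## Phenotypic local adaptation

`fit_gxe()` fits `trait ~ soil_line * soil_grown + (1 | replicate)` by
REML, tests fixed terms with type-III Wald chi-squares (sum-to-zero
contrasts), and reports the four cell means with their covariance. A
replicate variance estimated at the boundary (zero) is reported as such.
Contrast estimates use the fixed-effect covariance with residual degrees
of freedom — simple and deterministic; with groups of ~300 plants the
difference from finite-sample df corrections is negligible. In the
balanced 2-soil × 2-line design the "local vs foreign" and "home vs away"
contrasts reduce to the same combination of cell means,
½(LL + TT) − ½(LT + TL); both rows are reported because the criteria are
conceptually distinct and diverge in richer designs. The verdict
`adapted` requires a significant interaction *and* a significantly
positive local-over-foreign contrast at α = 0.05, with no multiple-testing
correction across traits (a single pre-declared fitness proxy is tested).

Trait–fitness association uses two models because seed set is
zero-inflated under pollen limitation (about half the plants set no
seed): a binomial GLM on seeds/no-seeds and a plain linear model on the
seed-producing subset. "Truncated regression" here means the latter —
the estimator behind that phrase is ambiguous, and at these sample sizes
a truncated-likelihood variant changes nothing material; the plain-subset
model is the transparent choice. Complete separation in the binary model
is flagged and the coefficient reported as non-estimable rather than as a
number. Bumblebee first choices use a Poisson log-linear model;
the visit–seed-set product-moment correlation is reported.
`trait_evolution()` compares generations within treatment (native-soil
plants only, foreign-grown plants excluded with a logged count) via a
mixed model with generation × treatment fixed effects.

## Numerical choices

* Strict vs inclusive bounds follow the conventional semantics of the
  standard filtering tools: QUAL strictly > 20, depth 6–100 inclusive,
  maf ≥ 0.01 inclusive; depth is judged per genotype by default, per site
  (mean depth) behind a flag.
* Window pruning tie-break: smallest position. Largest-remainder ties:
  first index in remainder order (deterministic).
* Monomorphic-in-all-strata markers: statistic 0, p = 1, never an error.
* All simulation randomness flows from one root seed through a
  deterministic per-stream hash, so replicates are independent but every
  run is bit-reproducible; seeds stay below 2³¹.
* Percent rounding is half-up (not banker's), matching the reporting
  style of the field.

## Problem sizes

The validation suites run at desk scale, chosen as the package's own
benchmark sizes: type-I calibration on 5,000 neutral markers × 10 seeds;
effect recovery on 20 panels of n = 150 × 200 markers; the end-to-end
study on one full default experiment (186 loci, 16 lines, 9
transmissions) with classification evaluated on the bee-pollination
groups; G×E power on 20 simulated transplant tables of 75 plants per
cell. The whole test suite runs in well under a minute.

## What the synthetic validation does not show

The generator emulates the experimental *design*, not the organism. It
assumes free recombination (the 2-kb pruning stage is exercised through
assigned positions, not simulated linkage), a Gaussian additive trait
(under the strong-selection scenario phenotypic divergence is exaggerated
and simulated flower counts can leave their natural range — a count model
would be needed for realistic trait values), no maternal effects beyond
the contribution formula, no bee learning or frequency-dependent
visitation, no soil microbiome or plasticity, and selection coefficients
constant across generations. Passing the suite therefore demonstrates
that the *inference machinery* is correct and calibrated under the stated
generative assumptions — it does not certify the biological conclusions
reachable from any particular real dataset, and real-data marker counts
are not reproduced here (they require the original sequence deposit).
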