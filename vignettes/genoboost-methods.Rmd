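---
title: "Boosted polygenic scores with genetic dominance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boosted polygenic scores with genetic dominance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A polygenic score (PGS) summarizes an individual's genetic liability for a
trait as a sum of per-variant contributions. Most PGS methods assume each
variant acts additively: the heterozygote effect is exactly half the
homozygote effect. Genetic dominance — any departure of the heterozygote
from that midpoint, spanning dominant, recessive, over-dominant and
over-recessive patterns — is real and trait-dependent, particularly in
autoimmune disease, but additive GWAS summary statistics cannot carry it.
This package fits binary-trait PGS models directly on individual-level
genotypes so that each selected variant can receive three free
genotype-dependent scores, one per dosage class.

## The boosting model

Let $y_i \in \{-1,+1\}$ be case/control labels and $g_{ij} \in \{0,1,2\}$
the minor-allele dosage of variant $j$ in sample $i$. The model is a
staged additive expansion on the logit scale,

$$F_{t+1}(x) = F_t(x) + \gamma\, f_t(x), \qquad
  F_0(x) = F_{\mathrm{cov}}(x),$$

where $F_{\mathrm{cov}}$ is the linear predictor of a covariate-only
logistic regression (fit by damped Newton iterations, with covariates
variance-standardized) and each weak learner $f_t$ depends on one variant's
genotype only. At iteration $t$ the current fit defines, per sample, the
Newton quantities of the logistic loss

$$p_i = \frac{1}{1+e^{-F_t(x_i)}},\qquad
  z_i = \begin{cases} 1/p_i & y_i = +1\\ -1/(1-p_i) & y_i = -1\end{cases},
  \qquad w_i = p_i(1-p_i),$$

and per genotype class $k \in \{0,1,2\}$ of each variant the sufficient
statistics $W_k = \sum_{i: g_i = k} w_i$, $U_k = \sum_{i: g_i = k} w_i z_i$
(missing genotypes contribute to no class). Every screened variant is
scored by the weighted least-squares loss
$\sum_i w_i (f(g_i) - z_i)^2$ of its optimal score triple, which has closed
forms:

* **Non-additive:** $s_k = U_k / W_k$, the $w$-weighted mean of $z$ within
  class $k$ — the unrestricted minimizer.
* **Additive:** $f(k) = c + \alpha k$ with

$$c = \frac{(W_1 + 4W_2)U_0 + 2W_2 U_1 - W_1 U_2}
           {W_0 W_1 + W_1 W_2 + 4 W_2 W_0},\qquad
  \alpha = \frac{-(W_1+2W_2)U_0 + (W_0-W_2)U_1 + (2W_0+W_1)U_2}
                {W_0 W_1 + W_1 W_2 + 4 W_2 W_0},$$

  the weighted least-squares line through the class means. The test suite
  checks these against a direct numerical solve of the normal equations and
  verifies the nesting
  $\mathrm{loss}(\text{non-additive}) \le \mathrm{loss}(\text{additive})
  \le \mathrm{loss}(\text{best constant})$ on every screened variant.

The variant with the smallest loss is selected (ties break to the smallest
index, so reruns are bit-identical), its scores are shrunken by the
learning rate $\gamma$ and added to the model; a variant may be selected
repeatedly and its contributions accumulate. Summing $\gamma f_t$ per
variant collapses the model to one cumulative triplet $(S_0, S_1, S_2)$
per selected variant; predictions from the collapsed table equal
predictions from the iteration-ordered learner list.

Fitting the additive and the unrestricted ("non-additive") variant of the
model and choosing between them on validation performance is the package's
model-type selection: the additive model wins on architectures without
dominance, the non-additive one when recessive or heterozygote-specific
effects carry signal.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `gamma` | 0.1 | learning rate in (0,1]; smaller = slower, better regularized |
| `iterations` | 100 | boosting steps `T`; the effective sparsity control |
| `m_batch` | 50 | batch size for screening on wide data (below) |
| `s2_clip` | off | clamp on the homozygous-minor score: forces the per-learner triple to satisfy two-sided bounds on `s2 - s0` |
| `z_max` | 1e8 | numerical clip on the working response |
| `w_floor` | 1e-10 | numerical floor on the working weights |

`s2_clip` is defined on the baseline-relative scale, clamping
$|s_2 - s_0|$, because the raw triplet carries an arbitrary intercept: the
quantity of scientific interest is the homozygous-minor effect relative to
the homozygous-major baseline. Homozygous-minor classes are the smallest,
so their raw class means have the highest variance; a modest clamp
regularizes exactly that term.

**Why `z_max` is a guard, not a regularizer.** The classical LogitBoost
stabilization caps $|z|$ at 4. For unclipped responses the products
$w_i z_i$ equal the logistic-loss gradient entries $y^*_i - p_i$ exactly,
so each class mean is a damped Newton step and the training log-loss
decreases monotonically in practice. A tight cap breaks that identity for
badly classified samples and we observed genuine ascent steps in the
training loss under a cap of 4 on long runs. The default therefore places
the clip far outside the reachable range, keeping it purely as an overflow
guard; both bounds remain configurable.

**Batch screening.** When the variant count exceeds `full_scan_max_d`
(default 10,000), a full scan over all variants runs at iteration 0 and
every `m_batch` iterations; between full scans, selection is restricted to
the `m_batch` best variants of the last full scan. This refresh rule is
this package's concrete choice; at desk scale (d below the threshold)
every iteration scans everything and the rule is inert.

**Empty genotype classes.** In non-additive mode an empty class carries no
weight, so any value leaves the loss unchanged; the score is imputed from
the nearest populated class (class 2 from $s_1$, class 0 from $s_1$, class
1 from the midpoint of $s_0, s_2$) to keep the score function total for
prediction on new samples. Additive mode instead skips variants with at
most one populated class, for which the slope is unidentified.

## Cross-validation and hyperparameter search

Samples are split once into a held-out test fraction (default 20%) and
`k = 5` folds over the remainder, without using phenotypes. The default
grid holds four learning rates (0.05, 0.1, 0.2, 0.5) and 29 iteration
counts (5, 10, 20…100, 200…1000, 2000…10,000) for each of the two model
kinds — 232 cells. Because boosting is a deterministic prefix algorithm,
one run at the largest `T` per (rate, kind) yields every grid snapshot
along its path; the package exploits this instead of refitting per cell.
The validation metric is the covariate-adjusted pseudo-R², computed on the
held-out fold only. Ties break toward smaller `T`, then smaller rate, then
the additive kind — the sparser, more regularized model. Per-fold winners
may differ; all fold models are retained and the first fold is designated
primary for interpretation.

## Evaluation metrics

The primary metric is the covariate-adjusted pseudo-R²
$$R^2 = \frac{1 - (L_{\mathrm{covars}}/L_{\mathrm{full}})^{2/n}}
             {1 - L_{\mathrm{covars}}^{2/n}},$$
with $L_{\mathrm{covars}}$ and $L_{\mathrm{full}}$ the evaluation-set
likelihoods of a covariate-only and a covariate-plus-score logistic model
whose coefficients were fit on a separate fitting set (the validation
fold) and frozen. Likelihoods are handled in log space and exponentiated
only inside the $2/n$ power, so large $n$ cannot underflow. Top-$q$ odds
ratios (defaults 1, 3, 5, 10%) compare case odds in the top
$\lceil qn \rceil$ scores against the remainder, with ties at the cut
broken by stable sample order and zero cells reported as errors rather
than silent infinities. AUC uses the Mann–Whitney formulation (ties count
one half); AUPRC is non-interpolated average precision with tied scores
treated as a single operating point, so a constant score scores exactly
the case fraction.

## Mode-of-inheritance inference

For a cumulative triplet $(S_0, S_1, S_2)$ define the dominance position
$\theta = (S_1 - S_0)/(S_2 - S_0)$: exactly 0.5 for a purely additive
variant, 1 when the heterozygote matches the homozygous-minor effect, 0
when only homozygous-minor carriers deviate. The classifier labels a
variant additive when $|\theta - 0.5| \le \tau_{add}$ (default 0.125),
dominant for $\theta \in (0.5+\tau_{add},\, 1+\tau_{over}]$, recessive for
$\theta \in [-\tau_{over},\, 0.5-\tau_{add})$ (default
$\tau_{over} = 0.25$), and over-dominant/over-recessive when the
heterozygote score falls outside the homozygote hull by more than the
margin, labelled by whether it lies above or below. Under allele
relabelling the triplet reverses and $\theta \mapsto 1-\theta$, so
dominant and recessive swap while the other labels are fixed — exactly
the behavior required for consistency with re-orienting the minor allele.
The thresholds are configuration, not constants: they are this package's
concrete instantiation of "deviation from linearity", and no claim is made
that they match any external tool's bands.

The independent comparator refits, per variant, one logistic regression
per genotype coding — dosage, `1{g>=1}`, `1{g==2}`, `1{g==1}` — with
covariates, and takes the coding with the smallest two-sided Wald p-value;
the heterozygote-only coding maps to over-dominant or over-recessive by
its coefficient sign. Plain damped-Newton logistic regression is used
throughout, without a penalized fallback for separation: fits that do not
converge are dropped from the comparison with a warning, which is a known
fidelity gap relative to pipelines that switch to penalized estimation.
Both a five-class and a collapsed three-class (additive/dominant/
recessive) comparison are available, since heterozygote-specific labels
are not always distinguished downstream.

## The synthetic cohort generator

The generator emulates the minimal structure the method needs: biallelic
SNVs in Hardy–Weinberg proportions with independent variants, and a binary
trait from a liability-threshold model,
$$L_i = \sum_j \beta_j\, a_j(g_{ij}) + \varepsilon_i,\qquad
  \varepsilon_i \sim N(0, 1-h^2),\qquad
  \beta_j \sim N(0, h^2/n_{\mathrm{causal}}),$$
where $a_j$ is the mode-specific encoding (dosage; `1{g>=1}`; `1{g==2}`;
`1{g==1}` with the effect sign forced positive for over-dominant and
negative for over-recessive modes) standardized to mean 0, variance 1
in-sample. Cases are the $\lceil \mathrm{prevalence}\cdot n\rceil$
largest realized liabilities — an empirical-quantile rule chosen over
stochastic penetrance so the case count is exact and one noise source is
removed from the recovery experiments. Mode composition is fixed by
largest-remainder rounding of `dominance_fraction` times the mode
weights, so a configuration always yields the same number of variants per
mode.

Defaults were chosen once: allele frequencies uniform on [0.1, 0.5],
because recessive effects are only estimable when homozygous-minor
carriers are non-negligible at desk-scale $n$ (at frequency 0.1 and
$n = 2000$, about 20 carriers), and no genotype missingness (the QC path
is exercised by hand-built fixtures instead).

What the generator deliberately omits: linkage disequilibrium, population
structure and relatedness, frequency-dependent effect-size coupling, and
covariate-phenotype confounding. Passing recovery tests on these cohorts
therefore demonstrates correctness of the fitting machinery — selection,
closed forms, classification — not robustness to the correlation
structure of real genotype panels, where LD makes "which variant in a
locus is selected" ill-determined.

## Problem sizes used by the tests and the acceptance study

The bundled experiments run at sizes a workstation handles in seconds to
minutes, chosen as the smallest cohorts at which the studied effects are
comfortably resolvable: the recovery study uses $n = 2000$, $d = 500$, 10
causal variants (3 recessive, 2 dominant, 5 additive) at $h^2 = 0.5$,
prevalence 0.3, five seeds, with non-additive fits at $\gamma = 0.1$,
$T = 200$; the model-choice and concordance studies use $n$ = 600–2000
and $d$ = 60–300. Larger panels change runtimes, not code paths.

## Known limitations

* Binary phenotypes only; no quantitative-trait loss.
* No variant–variant interaction terms; dominance is within-variant.
* The GWAS comparator's plain logistic fits lose power under separation.
* Classification bands are heuristic configuration; boundary variants
  (e.g. $\theta$ near $0.5 \pm \tau_{add}$) switch labels under small
  refits.
* The batch-screening refresh rule is a documented approximation suited
  to very wide panels; results below the full-scan threshold are exact.
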