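---
title: "Drug-target Mendelian randomization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Drug-target Mendelian randomization (MR) asks whether pharmacological
modulation of a specific protein is likely to affect a disease outcome, using
genetic variation as a natural experiment. Variants in or near the gene
encoding a drug's target protein perturb that protein much as the drug does;
their association with a downstream biomarker of the drug (here: blood
glucose for antidiabetic drug classes) calibrates the perturbation, and their
association with the disease (here: rheumatoid arthritis, a case-control
trait on the log-odds scale) measures its consequence. `targetmr` implements
the full analysis as a pipeline over GWAS summary statistics: cis-instrument
selection, two-sample harmonization, causal-effect estimation, a
positive-control direction gate, and regional colocalization, together with a
generator of synthetic summary statistics so every stage is testable without
any external downloads.

## Model and estimators

For instrument $j$, let $\hat\beta_{Xj}$ (se $\sigma_{Xj}$) be its per-allele
effect on the exposure and $\hat\beta_{Yj}$ (se $\sigma_{Yj}$) its per-allele
log-odds effect on the outcome, aligned to the same effect allele. Under the
instrumental-variable assumptions each ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the causal log-odds
of outcome per exposure unit, with first-order (delta-method) standard error
$\sigma_{Yj}/|\hat\beta_{Xj}|$ — the two-sample convention, which neglects
exposure-side error; the second-order form is available via
`wald_ratio(..., second_order = TRUE)`.

* **Wald ratio** (one instrument): the ratio itself.
* **Fixed-effect IVW** ($k \ge 2$):
  $\hat\theta = \sum_j w_j \hat\theta_j / \sum_j w_j$ with
  $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$ and
  $\mathrm{se} = (\sum_j w_j)^{-1/2}$. With $k = 1$ this reduces exactly to
  the Wald ratio (tested to $10^{-12}$).
* **MR-Egger** ($k \ge 3$): weighted least squares of $\hat\beta_Y$ on
  $\hat\beta_X$ *with intercept*, weights $1/\sigma_Y^2$, after orienting
  every instrument so $\hat\beta_X \ge 0$ (the estimator is not
  orientation-invariant otherwise). The slope estimates the causal effect
  under the InSIDE assumption; the intercept estimates average directional
  pleiotropy. Standard errors use a multiplicative dispersion floored at 1.
* **Weighted median** ($k \ge 3$): the 0.5 point of the weighted empirical
  distribution of the $\hat\theta_j$, interpolating linearly on cumulative
  weights $s_j = \sum_{i \le j} w_i - w_j/2$. Consistent when instruments
  carrying half the weight are valid.
* **Weighted mode** ($k \ge 3$): argmax of a weighted normal-kernel density
  over the $\hat\theta_j$, bandwidth
  $h = \phi\, 0.9 \min(\mathrm{sd}, \mathrm{MAD}) k^{-1/5}$ on a 512-point
  grid spanning the ratio range $\pm 3h$. Consistent under plurality
  validity.

Median and mode standard errors come from a parametric bootstrap (default
10,000 replicates) resampling $\hat\beta_X$ and $\hat\beta_Y$ from their
estimated sampling distributions; a seed is mandatory so they are exactly
reproducible.

Estimates are reported both per +1 exposure unit (log-odds) and as an odds
ratio per 0.1 unit *lower* exposure (`scale_factor = -0.1`, the
glucose-lowering convention; an alternative exposure such as log fasting
insulin uses `-1`). P-values are normal-theory and scale-invariant.
Significance is gated at $\alpha/m$ with a strict inequality; the default
$0.05/6$ drug classes prints as 0.008.

## Instrument selection

Per drug class, selection applies, in order:

1. **cis window**: variants inside the closed interval
   [gene start − 2.5 kb, gene end + 2.5 kb], unioned over genes for
   multi-gene targets (the two sulfonylurea genes are adjacent, and their
   windows are clumped jointly so correlated duplicates cannot enter).
2. **FDR**: Benjamini–Hochberg within the extracted window, keep $q < 0.05$.
   The adjustment set is the cis window — the only choice computable from a
   cis extract; a genome-wide adjustment would require the full GWAS.
3. **Palindrome rule**: A/T and C/G variants are strand-ambiguous and are
   admitted only with minor allele frequency below 0.3, so frequency can
   resolve the strand downstream.
4. **LD clumping**: greedy by ascending p (ties: position, then rsid, making
   the output order-invariant), discarding anything with $r^2 \ge 0.001$
   against a retained variant ($r^2 \ge 0.1$ in the relaxed sensitivity
   run). Greedy clumping at two thresholds is not nested by construction —
   a variant kept by an intermediate retainee can differ — but on the
   low-LD study scenarios the relaxed run is a superset, and the pipeline
   checks this.
5. **Proxy lookup**: instruments absent from the outcome dataset are
   replaced by the best panel variant present there with $r^2 > 0.8$
   (searched within the window plus 500 kb flanks; ties by distance then
   rsid), or dropped. The signed panel correlation travels with the proxy
   for allele mapping.

Every exclusion is logged once with a stage and reason code. Per-variant
instrument strength is $F = (\hat\beta/\mathrm{se})^2$; a mean $F \le 10$
raises a weak-instrument flag. Functional variants of established biological
relevance can be forced by rsid; they bypass FDR ranking and clumping but
not the palindrome/proxy checks, and are analyzed as separate instrument
sets.

## Harmonization

The outcome record is aligned to the exposure's effect allele: swapped
alleles negate $\hat\beta_Y$ and complement the frequency;
strand-complement matches (A/G vs T/C) are resolved before declaring
incompatibility. Palindromic pairs — for which swap and strand flip are
indistinguishable — align by frequency concordance (minimize
$|\mathrm{eaf}_X - \mathrm{eaf}_Y|$) and are dropped as ambiguous when both
frequencies lie in (0.42, 0.58), a standard safety band that the MAF < 0.3
admission rule makes rarely binding. Proxy alleles map through the sign of
the panel correlation: negative $r$ swaps the proxy's alleles first — the
only information a correlation panel can provide. Harmonizing a dataset
whose alleles have all been rewritten in the opposite orientation is an
involution: the harmonized effects, and all downstream estimates, are
identical to $10^{-12}$ (tested).

## Positive-control gate

Before the primary analysis, each drug class must reproduce established
pharmacology on control outcomes: T2DM risk must fall for every class;
weight-related traits must rise for insulin, thiazolidinediones and
sulfonylureas, fall for GLP-1 receptor agonists and SGLT2 inhibitors, and
are unconstrained for the weight-neutral DPP-4 inhibitors; insulin
resistance must fall for thiazolidinediones; fasting proinsulin must rise
for the insulin-secretagogue classes. Concordance is judged on the sign of
the point estimate only — the narrative criterion made operational; a
strict mode additionally requiring nominal $p < 0.05$ is available.
Untested outcomes are recorded, never counted as failures. A failed gate
suppresses the primary MR for that class.

## Colocalization

Whether the exposure and outcome signals in a significant region share one
causal variant is assessed with per-variant approximate Bayes factors:
$\log \mathrm{ABF} = \tfrac12\log(1-r) + \tfrac12 r z^2$ with
$r = W/(W + \mathrm{se}^2)$. The effect prior variance $W$ uses the
framework's standard defaults — $(0.15\,\mathrm{sd}_Y)^2$ for continuous
traits (sd estimated from the summary statistics via the null-variant
identity $\mathrm{var}(Y) \approx 2f(1-f)\,n\,\mathrm{se}^2$, median across
variants) and $0.2^2$ on the log-odds scale for binary traits. The five
hypothesis sums use priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ and
are evaluated in log space with log-sum-exp; the two-distinct-variants sum
uses the product-minus-diagonal identity rather than the $O(M^2)$ double
sum, clamping tiny negative cancellations to zero. The streamlined sums are
tested against exhaustive enumeration of all $1 + 2M + M^2$ causal
configurations for $M \le 10$. The region is the drug-target window plus a
200 kb flank, so the regional signal — not just the instruments — is
colocalized.

## The synthetic-data generator

Summary statistics are simulated directly from their asymptotic sampling
distribution rather than from individual-level genotypes — orders of
magnitude faster, and exactly the structure two-sample MR assumes. On the
standardized-genotype scale, with LD matrix $R$ and standardized causal
effects $b$:
$\hat b_X \sim \mathcal N(Rb,\; R\,\sigma_X^2/n_X)$ and
$\hat b_Y \sim \mathcal N(R(\theta b + a),\; R\,c/n_Y)$ with
$c = 1/(\varphi(1-\varphi))$ for case fraction $\varphi$ (logistic-score
variance approximation, whose adequacy is covered by the type-I-error band
rather than by exactness claims). Configured effects ($\beta$, $\alpha$)
are per-allele and are converted through $\sqrt{2f(1-f)}$. Standard errors
are the theoretical values (they scale exactly as $n^{-1/2}$), p-values are
two-sided normal, and the exposure and outcome draws are independent
(non-overlapping samples). Default sample sizes emulate a biobank-scale
glucose GWAS ($N = 309{,}895$) and an RA case-control GWAS (22,350 cases /
74,823 controls); a fraction of outcome records is emitted under the
opposite allele orientation so harmonization is genuinely exercised.

What the generator does *not* emulate: sample overlap, population
stratification, imputation noise, allele-frequency differences between
datasets, and genome-scale polygenicity. Passing calibration therefore
shows the estimators and pipeline are correct under the model's own
assumptions, not that real data meet those assumptions.

### Scenario presets and their calibration role

Presets place the region in the PPARG window and pin causal-variant MAFs at
0.25 so expected instrument strength is deterministic. The recovery presets
(`one-causal`, `multi-causal`; $n_X = 3\times10^5$, $n_Y = 10^5$,
$\theta = 0.2$) use top-tier cis effects (~0.08 exposure units per allele,
expected $F \approx 750$, the scale of the strongest glucose cis loci):
with 200 replicates the Monte-Carlo se of the mean IVW estimate is then
about 0.006, so a bias bound of 0.02 is a ~3 se statement rather than noise.
The weak-instrument regime is covered separately by its own preset
(expected $F \approx 8$). `directional-pleiotropy` injects a constant
per-allele direct effect $\alpha = 0.05$ across 20 instruments (Egger
intercept recovery); `balanced-pleiotropy` corrupts 40% of the weight
(median robustness while IVW is driven off); `shared-causal`,
`distinct-causal` and `null-region` drive the colocalization posteriors
toward H4, H3 and H0 respectively.

### Problem sizes used in the checks

Calibration runs use 200 replicates for recovery and coverage, 1,000 for
type-I error, 100 per colocalization scenario, 50 for the Egger intercept,
and null-uniformity Kolmogorov–Smirnov checks over 100 seeds at
$M = 1{,}000$ variants plus one run at $M = 5{,}000$ (the property is
independent of $M$, which only tunes KS power).

## Numerical choices and edge cases

* Clumping and proxy ties break deterministically (position, then rsid);
  reports are byte-identical across reruns with the same configuration and
  seed.
* p-values are floored at the smallest positive double so they stay in
  (0, 1].
* The weighted mode falls back to the common ratio when the bandwidth is
  degenerate, and to the positive spread measure if only one of sd/MAD is
  zero.
* $p_{12} = 0$ is accepted as an explicit prior exclusion of the shared
  configuration (PP.H4 = 0 exactly); a single-variant region has
  PP.H3 = 0 exactly because no two-distinct-variant configuration exists.
* Egger requires $k \ge 3$ and median/mode likewise; below that they are
  reported as not applicable, never errors. An empty instrument set is a
  `"no-instruments"` status, mirroring real drug classes whose cis windows
  contain no qualifying variants.
* With the intercept constrained to zero, the Egger weighted regression is
  algebraically identical to fixed-effect IVW (tested by refit).

## Known limitations

* The Wald/IVW standard errors ignore exposure-side sampling error (NOME);
  with the weak-instrument flag raised, estimates should be read as
  attenuated.
* The positive-control gate is a sign test by design; it inherits the
  direction conventions of the scaling factor.
* Colocalization assumes at most one causal variant per trait in the
  region; multiple causal variants dilute PP.H4.
* FDR within the cis window is the computable choice, but it is not
  identical to a genome-wide adjustment; with very small windows it is
  conservative.
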