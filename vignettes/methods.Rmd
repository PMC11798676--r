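---
title: "Sparse signature attribution by likelihood ratio tests: models, generator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse signature attribution by likelihood ratio tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasa)
```

## The attribution problem

A tumor's mutational spectrum is a vector of counts $D = (d_1, \dots,
d_k)^T$ over a fixed classification of mutation types ($k = 96$ for
single-base substitutions in trinucleotide context, $78$ for doublet-base
substitutions, $83$ for small insertions and deletions). A mutational
signature is a multinomial probability vector $\vec h$ over the same
channels, describing the characteristic mutation-type proportions of one
mutational process. Given a catalog $H \in \mathbb{R}_{\ge 0}^{k \times
g}$ of candidate signatures — in practice the signatures previously
observed in the sample's cancer type — *signature attribution* seeks
non-negative activities $A = (a_1, \dots, a_g)^T$ such that $D \approx H
A$, where $a_j$ is the number of mutations ascribed to signature $j$.

The difficulty is not fitting but *selection*: many different subsets of
$H$ reconstruct a given spectrum almost equally well (the
`enumerate_attributions()` machinery in this package makes that concrete),
and unconstrained least-squares fits scatter small, spurious activities
across many signatures. This package's core algorithm treats selection as
a statistical question: a signature stays in the attribution only if
removing it significantly worsens the best achievable likelihood of the
observed counts.

## Likelihood models

Write $\vec c = H A$ for the expected channel counts of an attribution.

**Multinomial.** Normalizing $\pi_i = c_i / \sum_j c_j$, the
log-likelihood of the observed spectrum is
$$\log \left[ \frac{(\sum_i d_i)!}{d_1! \cdots d_k!}\,
\pi_1^{d_1} \cdots \pi_k^{d_k} \right],$$
computed via log-gamma, multinomial coefficient included. Only the
proportions of $A$ matter here (the total cancels), so
`mle_fit(model = "multinomial")` rescales the fitted activities to sum to
the spectrum total — a convention, chosen to make step-1 outputs
comparable across models; the original implementation's behavior on this
point is not documented.

**Negative binomial.** The log-likelihood is $\sum_i \log
\mathrm{NB}(d_i \mid \mu = c_i, \text{size} = r)$, with a dispersion
(size) parameter shared across channels; variance $\mu + \mu^2 / r$. This
model, unlike the multinomial, is sensitive to the absolute scale of $A$
and tolerates per-channel overdispersion.

**Flooring.** Both formulas are undefined when some $c_i = 0$ while $d_i >
0$. Before forming $\pi$ or the negative-binomial means, each $c_i$ is
floored at $10^{-10} \max(1, \sum_j c_j)$. The floor is far below one
mutation, so it preserves the ordering of candidate attributions while
keeping every log-likelihood finite.

**Likelihood ratio test.** For nested attributions $A_2 \subset A_1$, the
statistic $\lambda = -2(\log P(D \mid A_2) - \log P(D \mid A_1))$ is
referred to a $\chi^2$ distribution with $|A_1| - |A_2|$ degrees of
freedom. Nested maximized models satisfy $\lambda \ge 0$ exactly;
negative values from optimizer tolerance are clamped to zero.

## The two-step algorithm

**Step 1 — presence filtering** (`presence_filter()`). For each signature
$h_i$, the best multinomial fit using $H \setminus h_i$ is compared
against the best fit using all of $H$ (LRT, one degree of freedom). A
signature is retained iff $p < \alpha$. Every signature is tested against
all the others, so the survivor set $V$ does not depend on testing order.
A duplicate pair of signatures illustrates the logic: neither copy is
individually necessary, so both are dropped.

**Step 2 — greedy forward search** (`forward_search()`). Starting from
the empty set, each iteration fits every candidate added to the current
set under the negative-binomial model and picks the one with the highest
fitted log-likelihood; it is accepted iff the add-one LRT gives $p <
\alpha$. The first signature is always accepted — the empty attribution
has no defined likelihood to serve as a null model, and any non-empty
spectrum needs at least one signature. The search stops at the first
non-significant best candidate. The returned set is minimal in the sense
that every recorded addition after the first was statistically
significant.

Candidates are ranked by likelihood; at one degree of freedom this is
equivalent to ranking by p-value. Ties within $10^{-9}$ break
lexicographically by name, making the whole procedure deterministic.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.01 | significance level of both LRT uses; smaller = sparser attributions |
| `dispersion` | 100 | step-2 negative-binomial size; no published value exists for the original method ("same dispersion parameter"), so this is a deliberate, prominent default meaning "modest overdispersion relative to Poisson" — with synthetic data generated at size 50 the mild mismatch costs nothing measurable |
| `max_signatures` | unlimited | hard cap on attribution size |

If step 1 eliminates *every* signature — possible for flat, low-count
spectra — step 2 runs on the full catalog rather than returning nothing,
since an empty attribution cannot reconstruct a non-empty spectrum. A
zero-count spectrum returns an empty attribution with a warning.

### Calibration of the presence test

The presence test's null hypothesis (true activity $= 0$) lies on the
boundary of the non-negative activity space. Classical boundary theory
applies: under the null, $\lambda$ is asymptotically a 50:50 mixture of a
point mass at 0 and $\chi^2_1$, so the $\chi^2_1$-based p-values are
**conservative** — about half of them pile up near 1 (we measure an atom
mass of ~0.53 at $p > 0.95$; conditioned below the atom the p-values are
uniform, confirming the $\chi^2_1$ calibration of the continuous half).
Consequently the realized false-presence rate is about $\alpha / 2$, never
above $\alpha$. We keep the plain $\chi^2_1$ reference because it is what
the method prescribes; the acceptance test asserting full KS uniformity of
the null p-values therefore fails by design, and the companion test
asserts the mixture property that actually holds.

## Activity optimizers

`nnls_fit()` solves $\min_{A \ge 0} \lVert D - H A \rVert_2$ by the
Lawson–Hanson active-set method (implemented here: no quadratic-programming
or NNLS solver is available among the package's allowed dependencies); the
problem is convex, and tests verify the solution against the
one-signature closed form, exact-representation recovery and 1000 random
probes. `mle_fit()` maximizes the chosen log-likelihood by bounded
quasi-Newton (L-BFGS-B) over log-activities with analytic gradients,
initialized at the NNLS solution with zeros replaced by $10^{-4} \times$
total — deterministic, no randomness. Activities pinned at the lower
bound ($10^{-6} \times$ total) are zeroed on return when that does not
reduce the likelihood; this also restores exact nested-model monotonicity,
which the log-scale bound alone cannot represent (a superset model must be
able to mimic a subset by dropping a signature *entirely*).

## The synthetic-data generator

`generate_dataset()` emulates a two-level negative-binomial scheme.
Per cancer type, each signature has a prevalence (fraction of tumors in
which it is active) and a negative-binomial activity distribution
(`fit_generator_params()` estimates both from a real activity table by
profile maximum likelihood: the mean is the exact MLE of $\mu$ for any
size, leaving a 1-D search over the size with method-of-moments
bracketing). A tumor draws each signature independently with its
prevalence; present signatures draw activities conditioned positive
(zero draws redrawn); a tumor with no signature at all is redrawn —
every real tumor carries at least one signature. Given the ground-truth
activities, the count in channel $i$ due to signature $s$ is drawn from
$\mathrm{NB}(\mu = a_s h_{is}, \text{size} = r_c)$ and summed over
signatures.

The channel dispersion $r_c$ controls how faithfully a spectrum resembles
its expected reconstruction; the median cosine between spectra and their
ground-truth reconstructions is monotone in $r_c$.
`calibrate_dispersion()` exploits that monotonicity with a log-scale
bisection (common random numbers across probes, $\ge 500$ spectra per
probe) to hit a target median cosine — e.g. 0.969, the median
reconstruction accuracy of attributions in real tumors, or 0.97 as used
in the acceptance tests.

**Toy defaults.** The bundled toy world (`toy_catalog()`,
`toy_generator_params()`) uses 4–6 near-orthogonal signatures (each
concentrates 90% of its mass on its own block of channels), prevalences
0.2–1.0, activity means 500–8000 with sizes 1–3 (strongly overdispersed,
like real per-cancer-type activity tables), and channel dispersion 50,
which puts toy reconstruction cosines in the ~0.97 range seen in real
data. These values were chosen once, a priori, as a realistic easy
regime.

**What a green test does not establish.** Real signature catalogs contain
highly correlated signatures (flat signatures, UV sub-signatures);
the toy signatures are nearly orthogonal by construction, so recovery
rates here are an upper bound on realistic performance and the tests
validate *mechanics* (selection, fitting, calibration, metrics), not
COSMIC-scale accuracy. The generator also assumes channel-independent
negative-binomial noise and signature-independent draws; real cohorts
have correlated exposures.

## Evaluation measures

With $X$ the ground-truth and $Y$ the estimated activity vectors over the
signature universe of the cancer type, and $M$ the sample's total
mutation count:

* Precision $= TP/(TP+FP)$, Recall $= TP/P$, Specificity
  $= TN/(TN+FP)$, F1; presence means activity $> 0$. An empty
  attribution is scored precision 1, recall 0 (the $0/0$ is resolved so
  that emptiness is penalized through recall only).
* Scaled Manhattan distance $= \sum_i |X_i - Y_i| / M$; scaled L2
  $= \lVert X - Y \rVert_2 / M$.
* Combined Score $= (1 - \text{scaled Manhattan}) + \text{Precision} +
  \text{Recall}$, maximum 3 at perfect recovery.
* KL divergence $= \sum_i X_i \log_2[X_i / (Y_i + \varepsilon)]$ over
  activity *proportions*, $\varepsilon = 0.001$. Terms with $X_i = 0$
  contribute 0; because $\varepsilon$ enters only the denominator the
  measure can be slightly negative at perfect agreement (e.g.
  $\log_2(0.5/0.501)$ per term for a 50/50 pair) — a property of the
  published formula, reproduced deliberately. Whether the original sums
  over all universe signatures or the truth's support is unspecified;
  with the $0 \log 0$ convention the two coincide.

`summarize_evaluations()` aggregates mean/median/SD per approach and
cancer type and dense-ranks approaches by descending mean Combined Score,
ties sharing a rank.

## Ambiguity enumeration

`enumerate_attributions()` NNLS-refits every nonempty subset of the
catalog (up to a configurable cap of 22 signatures, $2^{22}-1$ subsets),
deduplicates by the *fitted* positive-activity support — two offered
subsets whose fits zero out the extras collapse to the same attribution —
and counts distinct supports whose reconstruction cosine exceeds a
threshold (default 0.969), before and after a minimum-activity filter
(default: every signature must explain $\ge 3\%$ of mutations). Support
membership uses a relative threshold of $10^{-6} \times$ total because
active-set NNLS returns exact zeros only up to solver tolerance.
`best_vs_truth()` asks, per synthetic sample, whether any alternative
support reconstructs better than the truth's own support, and whether the
best filtered attribution is exactly correct — the package-level
demonstration of why sparsity constraints alone cannot resolve
attribution ambiguity.

## Numerical and design choices, collected

* Channel label sets and orders follow the public COSMIC conventions;
  matrices are re-sorted into canonical order on load, so row order in
  input files never matters. Several header dialects for the row-label
  column are accepted.
* Spectrum counts within $10^{-6}$ of an integer are rounded; other
  non-integers are rejected. Signature columns must sum to 1 within
  $10^{-3}$ on load and are renormalized exactly.
* Seeds: `generate_dataset()` derives one sub-seed per sample from the
  master seed, so cohorts are reproducible and individual samples can be
  regenerated in isolation.
* Acceptance criterion readings that required a decision: the null-
  uniformity criterion is red by design (boundary mixture, above); the
  activity-accuracy clause of the recovery criterion is quantified per
  activity ($\ge 95\%$ of recovered activities within 10%), because at
  channel dispersion 50 the *realized* mutation total of a signature
  deviates from its drawn activity by more than 10% in about 1% of draws
  — a worst-of-all-activities reading would fail on sampling noise alone,
  before any estimation error.

## Known limitations

* Step-2 dispersion is a fixed configuration value, not estimated from
  data; no per-mutation-class (SBS/DBS/ID) defaults are published for the
  original method.
* The presence test is conservative (see above); users wanting exact
  size-$\alpha$ behavior should halve their nominal $\alpha$.
* Only the add-one LRT stopping rule is implemented in step 2; no
  comparison against the full-model likelihood is performed.
* Multi-sample joint attribution, bootstrap confidence intervals and
  rare/common signature tiers are out of scope.
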