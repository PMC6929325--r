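---
title: "Testing the significance of Jaccard/Tanimoto similarity"
author: "jaccardtest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing the significance of Jaccard/Tanimoto similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jaccardtest)
```

## The model

Presence-absence data record whether each of two species occurs (1) or
not (0) in each of $m$ biogeographic units — islands, habitats, survey
sites.  The Jaccard/Tanimoto coefficient
$T(\mathbf{y}_i, \mathbf{y}_j)$ is the ratio of the intersection to the
union of the two binary vectors.  Under the null model of independence,
each vector is i.i.d. Bernoulli with occurrence probabilities $p_i$ and
$p_j$, and the cell counts $(N_1, N_2, N_3, N_4)$ of the $2\times 2$
pattern table — both present, only the first, only the second, neither —
are jointly multinomial with cell probabilities
$(p_i p_j,\; p_i(1-p_j),\; (1-p_i)p_j,\; (1-p_i)(1-p_j))$.

Because $T = N_1/(N_1+N_2+N_3)$ is undefined when the union is empty, the
refined coefficient assigns that case the expectation under independence,

$$\mathbb{E}[T] \;=\; \frac{p_i p_j}{p_i + p_j - p_i p_j},$$

which follows from $N_1 \mid N_1+N_2+N_3$ being binomial with success
probability exactly $\mathbb{E}[T]$.  The *centered* coefficient
$T^c = T - \mathbb{E}[T]$ makes the sign interpretable: negative values
are fewer co-occurrences than chance, positive values more.  The test is
two-sided: $H_0\colon T^c = 0$ against $H_1\colon T^c \neq 0$.

## The four p-value engines

**Exact** (`jaccard_test_exact`).  The p-value is the null mass of the
critical region — all multinomial states whose statistic is at least as
extreme as the observed one.  With $p_i, p_j$ unknown they are estimated
by $\hat p = \sum y / m$, which creates a subtlety: plugging $\hat p$
into the expectation *inside the region* biases the expectation toward
the observed coefficient and makes the test conservative.  The region
statistic is therefore re-centered per state, using that state's own
plug-in estimates $\tilde p_i = (N_1+N_2)/m$, $\tilde p_j = (N_1+N_3)/m$,
while the null mass itself is measured by the multinomial pmf at the
observed data's $\hat p_i, \hat p_j$.  States with an empty union are
given statistic 0 (their coefficient equals its expectation by the
refined definition).  The comparison is inclusive ($\geq$) with an
absolute floating guard of $10^{-12}$ so exact ties are never dropped.
The enumeration covers $\binom{m+3}{3}$ states and is refused above a cap
(`options(jaccardtest.exact_cap = 1000)`).

**Asymptotic** (`jaccard_test_asymptotic`).  Writing $q_1 = p_i p_j$ and
$q_2 = p_i + p_j - 2 p_i p_j$, the multinomial CLT and the delta method
applied to $g(x_1, x_2) = x_1 / (x_1 + x_2)$ give
$\sqrt{m}\, T^c \to \mathcal{N}(0, \sigma^2)$.  Carrying the algebra
through exactly,

$$\nabla g \,\Sigma\, \nabla g^{\top}
  = \frac{q_1 q_2^2 (1-q_1) + 2 q_1^2 q_2^2 + q_1^2 q_2 (1-q_2)}{(q_1+q_2)^4}
  = \frac{q_1 q_2}{(q_1+q_2)^3},$$

which is what the Monte-Carlo variance of $\sqrt{m}\,T^c$ converges to
(`asymptotic_variance(..., corrected = TRUE)`; the acceptance script
checks this at $m = 2000$).  The classical form quoted for this
statistic carries an extra factor $(1 - q_2)$; at $p_i = p_j = 0.5$ it is
half the true variance, which inflates $|z|$ and makes the test
anti-conservative precisely at mid-range occurrence probabilities, and
(combined with the plug-in correlation between $T$ and
$\hat{\mathbb{E}}[T]$, which the normal approximation ignores) leaves it
conservative at high ones.  `jaccard_test_asymptotic` defaults to the
classical form deliberately: it reproduces the operating characteristics
this method is known for, and the package treats it as a speed fallback,
not a recommended engine.  The two-sided p-value is
$2(1 - \Phi(|z|))$ — an expression of the form $2\phi(z) - 1$ is the
coverage of the central interval, whose complement is the p-value.

**Measure concentration** (`jaccard_test_mca`).  The multinomial
concentrates around its mode, so a set $I_\varepsilon$ with
$\mathbb{P}(I_\varepsilon) \geq 1-\varepsilon$ can be built greedily:
start at the mode (hill climbing from the rounded mean; the pmf is
unimodal over one-unit moves between cells, so the local maximum is
global) and repeatedly accept the highest-probability unvisited neighbor
(best-first over the frontier) until the accumulated mass reaches
$1-\varepsilon$.  Summing the pmf of the accepted states that fall in
the critical region gives a lower bound $p^L$ with
$p^L \le p_{\text{exact}} \le p^L + \varepsilon$ and
$p^U - p^L = \varepsilon$ by construction.  The reported p-value is
$p^L$; both bounds sit in `extras`.  The per-state statistic and tie
guard are shared with the exact engine (one C++ function), so the
sandwich holds to summation rounding.  Default
$\varepsilon = 10^{-5}$.

**Bootstrap** (`jaccard_test_bootstrap`).  Resampling the $m$ positions
of each vector with replacement, separately for the two vectors, breaks
any dependence while preserving the marginal occurrence frequencies.
The expectation is re-estimated from each resampled pair, which avoids
centering on the observed sample.  The empirical p-value uses the
pseudocount rule $(1 + \#\{|T^{c*}_b| \ge |\hat T^c|\})/(B+1)$: p-values
are never zero and the test errs slightly conservative.  Default
$B = 5m$ (5–10 times $m$ is recommended).  A resampled pair's counts are
multinomial at the observed plug-in cell probabilities and its statistic
is re-centered with its own estimates — exactly the exact test's measure
and region — so the bootstrap p-value converges to the exact one at the
binomial Monte-Carlo rate, which the tests exploit as an error bound.
For large screens, `pooled_null_pvalues()` pools null statistics across
pairs to raise the p-value resolution to $1/(n_{\text{pairs}} B + 1)$.

## Numerical and design choices

* **Region ties.**  The inclusive region comparison uses an absolute
  $10^{-12}$ guard in both the exact and MCA sums and in the bootstrap
  hit count; the centered-statistic identity is asserted at the same
  tolerance.  Region sums may exceed 1 by accumulated rounding
  ($\sim 10^{-15}$) and are clamped.
* **Degenerate inputs.**  A pair in which both vectors are all-zero
  carries no evidence against independence: the low-level functions
  refuse it, and the screening pipeline flags the pair and assigns
  p-value 1.  A vector that is all-zero (or all-one) against an
  informative partner is handled naturally: the observed statistic is 0
  and the p-value 1 (the asymptotic engine refuses instead, since its
  variance degenerates).
* **Mode start and repair.**  Hill climbing starts from the
  componentwise-rounded mean, repaired to sum $m$ through the largest
  cell.
* **Expansion order.**  Any complete neighbor expansion satisfies the
  $1-\varepsilon$ bound; best-first by pmf reaches it with the fewest
  states and is an efficiency choice, implemented with a priority queue
  and a bit-packed visited cube.
* **RNG contract.**  A seed determines all resamples; draws are
  pair-major in output order, vector 1 before vector 2 within a pair.
  Reproducibility is promised for this package's RNG, not bit-identical
  streams across implementations.
* **Scaling the coefficient by its variance** (to span a fixed range) is
  sometimes suggested alongside the centered coefficient; no standard
  definition of the scaled statistic exists and it is not implemented.

## Screening and FDR control

`pairwise_jaccard_test()` tests all $n(n-1)/2$ unordered pairs of rows
of a presence-absence matrix (lexicographic label order), after
`filter_species()` removes generalists (present everywhere) and
absentees — their occurrence estimates are degenerate ($\hat p \in
\{0,1\}$) and a 53-species survey across 28 islands, say, yields 1378
tested pairs.  Q-values follow the Storey approach: $\pi_0$ (the
proportion of true nulls) is estimated from
$\hat\pi_0(\lambda) = \#\{p > \lambda\} / (n(1-\lambda))$ on the grid
$\lambda = 0, 0.05, \ldots, 0.90$, extrapolated to $\lambda \to 1$ with
a cubic smoothing spline and clipped to $(0, 1]$; q-values are the
monotone step-up transform of $\hat\pi_0\, n\, p / \text{rank}(p)$.

Two estimator regimes matter in practice.  With thousands of tests the
smoother behaves well and is the `estimate_qvalues()` default.  With a
few hundred tests the spline's value at the endpoint rests on a handful
of order statistics; it is then both noisy and biased downward, and
because q-values scale inversely with $\hat\pi_0$, downward fluctuations
inflate the realized false discovery proportion.  The single-cutoff
estimator at $\lambda = 0.5$ is unbiased there (and is also the safer
choice for heavily discrete p-value supports, e.g. bootstrap p-values at
moderate $B$).  `run_fdr_study()` therefore scores with the fixed-cutoff
estimator by default; pass `pi0_method = "smoother"` to reproduce
large-screen behavior.

## What the simulation harness emulates — and what it does not

`simulate_null_pairs()` draws mutually independent i.i.d. Bernoulli
vectors: the null model itself, at the study design of 2000 pairs with
$m = 100$ and $p \in \{0.1, 0.3, 0.5, 0.7, 0.9\}$.
`simulate_mixture()` emulates the FDR design — one query vector, $n$
companions of which a fraction $\pi_0$ is independent — with a declared
dependence mechanism for the associated rest: each entry copies the
query with probability $\rho$ (default 0.5), else is a fresh
Bernoulli($p$) draw.  This preserves the marginal occurrence probability
and spans independence ($\rho = 0$) to identity ($\rho = 1$); it is a
design choice, so mixture results are comparable across engines but not
numerically to any particular published figure.  Real survey data differ
in ways none of this emulates: spatial autocorrelation between units,
heterogeneous occurrence probabilities across units, and network (not
hub-and-spoke) dependence among species.  Calibration passing on these
simulations therefore validates the null machinery, not robustness to
those violations.

Study sizes used by the test suite and acceptance script are desk-scale
choices: 2000 pairs per calibration scenario, and $n = 500$ companions
with 5 replicates per FDR scenario.

## Known limitations

* Null p-values are uniform to a KS test at mid-range occurrence
  probabilities, but at $p = 0.1$ or $0.9$ with $m = 100$ the expected
  occurrence count is small, the p-value support is coarse, and plug-in
  estimation shifts the mid-range of the null p-value distribution
  (the tails stay calibrated: rejection at $\alpha = 0.01$ remains at
  $\approx 0.01$).  A formal uniformity test rejects there even though
  the tests remain usable for significance calls; this affects the
  exact, MCA and bootstrap engines alike, because the three agree with
  one another by construction.
* The asymptotic engine is a documented-bias fallback (above); it should
  only be used when computing time is the bottleneck.
* Missing values are not supported: cells must be 0 or 1.
* Weighted/abundance data and other similarity measures (Sørensen,
  Ochiai) are out of scope.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
y1 <- rbinom(100, 1, 0.5)
y2 <- ifelse(rbinom(100, 1, 0.5) == 1, y1, rbinom(100, 1, 0.5))
jaccard_test(y1, y2)                       # mca engine, epsilon = 1e-5
jaccard_test(y1, y2, method = "exact")     # full enumeration
jaccard_test(y1, y2, method = "bootstrap", seed = 2)

# a full screen
mat <- matrix(rbinom(20 * 50, 1, 0.4), nrow = 20,
              dimnames = list(paste0("sp", 1:20), NULL))
res <- pairwise_jaccard_test(mat, method = "mca")
head(res[order(res$qvalue), ])
attr(res, "pi0")
```
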