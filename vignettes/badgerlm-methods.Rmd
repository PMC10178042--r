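---
title: "Methods: honey-badger-optimised ELMs for SWIR spectral classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: honey-badger-optimised ELMs for SWIR spectral classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(badgerlm)
```

## Problem and model

The package targets multiclass discrimination of surface treatments from
short-wave infrared (1000–2500 nm) diffuse-reflectance spectra — the
setting in which pesticide residues on fruit are screened non-destructively
from hyperspectral region-of-interest mean spectra. Each sample is one
233-channel reflectance vector with a label in five groups: an untreated
control and four pesticides (Acetamiprid, Malathion, Difenoconazole,
Beta-cypermethrin).

The classifier is an extreme learning machine (ELM): a single-hidden-layer
network whose input weights $\omega \in \mathbb{R}^{d\times L}$ and hidden
biases $b \in \mathbb{R}^L$ are *not* gradient-trained. With the logistic
sigmoid $\sigma$, the hidden design matrix is
$H_{ij} = \sigma(x_i \cdot \omega_j + b_j)$ and the output weights are the
least-squares solution $\beta = H^{+}T$ against one-hot targets $T$
($H^{+}$ = Moore–Penrose pseudo-inverse, computed by SVD via `MASS::ginv`).
Prediction is the row-wise argmax of $H\beta$, ties broken toward the
lowest class index. Targets are one-hot in $\{0,1\}$ — the conventional ELM
encoding; nothing in the method constrains the encoding, and argmax
decoding makes the scale irrelevant.

Because accuracy depends strongly on the random $(\omega, b)$ draw, the
package treats the packed vector (column-major $\omega$, then $b$; length
$dL + L$) as a continuous search space over $[-1, 1]^{dL+L}$ — the same
interval the random initialisation samples — and minimises an error-rate
fitness with a population metaheuristic.

## The honey badger algorithm and its t-mutation variant

HBA maintains $N$ agents $x_i$ and the best-so-far position $x_{prey}$.
Per iteration $t$ (1-based) with density factor
$\alpha = C\,e^{-t/t_{max}}$ ($C = 2$), each agent proposes one move,
choosing with probability 1/2 between

* digging:
  $x' = x_{prey} + F\,\beta_a I\, x_{prey} +
   F\,r_3\,\alpha\,d\,\lvert\cos(2\pi r_4)(1-\cos(2\pi r_5))\rvert$
* honey: $x' = x_{prey} + F\,r_7\,\alpha\,d$

where $d = x_{prey} - x_i$, $F = \pm 1$ with equal probability,
$\beta_a = 6$ is the digging-strength constant, and the smell intensity is
the inverse-square term $I = r_2 S / (4\pi d^2)$ with source strength
$S = (x_i - x_{i+1})^2$. Several details are genuinely open in the usual
statement of the algorithm; the package fixes them as follows and exposes
none of them as tuning dials:

* $S$, $d$ and hence $I$ are per-dimension vectors; $r_2,\dots,r_7$ are
  scalar per agent per move.
* The neighbour $x_{i+1}$ wraps: the last agent pairs with the first, so
  $S$ is defined for every agent.
* $d^2$ carries an additive guard of $10^{-12}$ so agents sitting exactly
  on the prey stay finite.
* Proposals are clamped to the box (positions decode to ELM weights that
  must stay in the sampled range) and accepted greedily — an agent only
  moves to a proposal that improves its own fitness; the prey updates
  whenever any evaluated proposal beats it.

tHBA adds, per agent per iteration with one Bernoulli($P$) gate
($P = 0.8$), the multiplicative mutation
$x' = x + x \odot t_{df=t}$: independent Student-$t$ draws per dimension
whose degrees of freedom equal the iteration number. At $t = 1$ this is
Cauchy noise (aggressive, heavy-tailed escape from local minima); as
$t \to \infty$ it approaches standard Gaussian refinement. Iterations are
1-based so the df is always valid. Mutants are clamped and accepted
greedily by default; `mutation_accept = "always"` preserves the alternative
reading in which the disturbed position always replaces the agent. Mutation
draws are skipped entirely when $P = 0$, so a tHBA run with $P = 0$
reproduces an HBA run bit-for-bit under the same seed — a reduction the
test suite asserts.

The GA baseline is real-coded with tournament selection (size 3),
arithmetic crossover (rate 0.8), per-gene Gaussian mutation (rate 0.05,
$\sigma = 0.1(ub-lb)$) and elitism of one — standard choices for a
continuous baseline; the original comparison protocol fixes only the
population (50) and iterations (300).

Every optimiser returns the best position, a per-iteration best-so-far
history (non-increasing by construction), and an exact evaluation count
($N(1 + t_{max})$ plus one per accepted mutation gate), which the tests
assert as bookkeeping invariants.

## Preprocessing

* Calibration: $R_c = (R_r - R_d)/(R_w - R_d)$ element-wise against
  all-white and all-black reference frames; coincident references raise an
  error naming the channel.
* MSC: each spectrum is OLS-regressed on a reference spectrum
  ($x \approx a + b\,\mathrm{ref}$) and corrected as $(x-a)/b$. The
  reference is the channel-wise mean of the *training* partition only —
  the protocol never states the fitting set, and fitting on training data
  alone avoids test-set leakage. $|b| < 10^{-12}$ raises an error rather
  than dividing by a near-zero slope.
* SNV: per-spectrum standardisation with the $n-1$ denominator (the
  conventional definition; documented so the worked examples are exact).
* Min-max (NM): per-spectrum rescaling to $[0,1]$. The axis is not stated
  in the usual description; row-wise is the default because it is
  invariant to per-sample gain and offset — exactly the distortions
  scatter introduces — and a per-channel variant is exposed but
  non-default.

## Metrics

Per-class metrics are one-vs-rest: precision $TP/(TP+FP)$, sensitivity
$TP/(TP+FN)$, F1 their harmonic mean. The per-class *accuracy* column
equals the sensitivity — the convention evidenced by every published
per-class row in this protocol (balanced classes) — while the strict
one-vs-rest accuracy $(TP+TN)/total$ is exposed separately as
`ovr_accuracy`. The overall ("All") row macro-averages precision,
sensitivity and F1 and reports the global correct/total as accuracy.
Zero denominators yield 0 with a warning rather than an error, because
small synthetic runs can leave a predicted class empty. Display rounding
(2 dp for percentages, 4 dp for F1) happens only in printing/writing;
internal values keep full precision. The shipped reference table of
published per-class rows lets the test suite and acceptance script verify
this arithmetic against independently printed numbers: all nine overall
rows re-derive from their class rows to within one unit in the last
printed digit.

## The synthetic generator

The original spectra are not publicly deposited, so the generator emulates
their documented statistical structure rather than any chemistry:

* a smooth quadratic baseline with signed Gaussian bumps
  ($\sigma$ = 35 nm, height 0.08) at the six reported peak wavelengths
  (1125, 1340, 1801, 2000, 2313, 2370 nm) and six valleys (1020, 1269,
  1552, 1929, 2432, 2466 nm);
* a class-dependent offset implemented as a raised-cosine bump supported
  exactly on 1493–2038 nm, the window where class differences are
  reported; defaults $(0, 0.05, 0.12, 0.07, 0.09)$ put the control lowest
  and Malathion highest (as observed) with the other pesticides at
  distinct intermediate levels — separable but overlapping under the
  default noise, so optimiser-vs-baseline comparisons are meaningful;
* per-sample affine scatter $a x + b$, $a \sim U(0.9, 1.1)$,
  $b \sim U(-0.05, 0.05)$, and additive channel noise with sd 0.02 —
  magnitudes a practitioner would call realistic for ROI-mean reflectance
  in $[0,1]$; the true intra-class variance is unpublished, so these are
  chosen for testability, not fidelity.

The generator does **not** model absorption chemistry, wavelength-dependent
scatter, instrument drift or pixel-level cube structure. Passing tests
therefore demonstrate that the algorithms behave correctly on data with
this covariance structure; they do not certify field performance on real
melon spectra.

The end-to-end checks also use a *well-separated* condition — offsets
$(0, 0.15, 0.60, 0.30, 0.45)$, i.e. inter-class gaps of 7.5× the noise sd —
under which a reduced-budget tHBA-ELM should recover ≥ 80 % test accuracy.

## Experiment protocol and design choices

`run_experiment` chains generation/loading → stratified 3:1 split
(per-class floor for the test count, so 160/class gives exactly 120/40) →
preprocessing fitted on the training partition → model fitting → test-set
metrics. The optimiser's fitness defaults to the error rate on an *inner*
validation slice (20 % of the training partition, stratified), because
scoring fitness on the test partition — as the original protocol describes
— leaks test labels into model selection. That historical behaviour is
preserved as `fitness_eval_set = "test_paper_mode"` for fidelity
experiments; the safe variant is the default. The final model always
retrains on the full training partition with the best $(\omega, b)$.

Hidden-layer sizes follow the protocol's conventions (135 for the plain
ELM, 120 for optimised models); both are plain config values. Full-scale
search (233 features × L = 120 → 28 080 dimensions, N = 50, 300
iterations) is supported but minutes-to-hours scale; the tests and the
acceptance script use reduced budgets chosen as the package's own
benchmark sizes — sphere benchmarks at N = 20, $t_{max}$ = 100, 10 seeds,
and end-to-end runs at L = 40, N = 10, $t_{max}$ = 30, 5 paired seeds —
which keep each property measurable in seconds while preserving the
qualitative orderings (tHBA ≤ HBA at equal evaluation budget on the
sphere; tHBA-ELM ≥ plain ELM on synthetic spectra).

## Numerical choices and degenerate inputs

* Pseudo-inverse via SVD with `MASS::ginv`'s default relative tolerance —
  robust when $L$ approaches $n$ and $H$ is near-singular; an optional
  ridge term is exposed for ill-conditioned problems but off by default
  (the method as described uses plain least squares).
* Sigmoid overflow is benign: $\sigma(-\infty) \to 0$ without NaNs.
* Constant rows are rejected by SNV/NM with the row index named;
  MSC rejects spectra uncorrelated with the reference.
* Equal-budget optimiser comparisons account mutation evaluations into the
  budget by construction (`n_evaluations`, `evals_history`).
* All stochastic components (generation, splitting, ELM initialisation,
  optimisers) are seeded independently and reproducibly; identical
  config + seed yields byte-identical output artifacts.

## Known limitations

* The generator's class structure is a single smooth offset bump; real
  pesticide spectra differ in richer, wavelength-localised ways, so
  absolute accuracies here do not transfer.
* Only the logistic sigmoid activation is implemented (the protocol's
  "sig"); kernel/online ELM variants are out of scope.
* SVM and PLS-DA baselines are not implemented; their published numbers
  are used only as metric-arithmetic fixtures.
* The HBA digging/honey equations follow the algorithm's source
  publication as adopted here; where that statement is ambiguous
  (dimensionality of $I$, the neighbour of the last agent, mutation
  acceptance) the choices above are interpretations, flagged as such.
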