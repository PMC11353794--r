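---
title: "Contrast information: a coordinate-invariant measure of information dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrast information: a coordinate-invariant measure of information dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contrastinfo)
```

## The measure

Cognitive models of sequential perception (melody, speech) track two
per-event signals: the *information content* (surprisal) of the observed
symbol, $-\log_2 p(y_n \mid \text{context})$, and the *entropy* of the
predictive distribution. Both quantify aspects of expectation and have strong
empirical support for discrete symbol streams, but neither survives the move
to continuous state spaces: a probability **density** rescales under any
smooth invertible change of coordinates, so the "information" of an
observation would depend on whether a pitch is described in Hz, log-Hz or
MIDI fractions. A measure fit for continuous percepts must be *coordinate
invariant*.

Relative entropy is coordinate invariant, and the specific-information form
of it gives a *dynamic* measure — one attached to a specific observation at a
specific moment. **Contrast information** is exactly that: given a target
regime $A$ of a stochastic process, a specific source observation $b$ and a
specific context $c$,

$$
I(A; b \mid c) \;=\; D\!\left(p(A \mid b, c)\,:\,p(A \mid c)\right)
\;=\; \sum_a p(a \mid b,c) \log_2 \frac{p(a \mid b,c)}{p(a \mid c)},
$$

with an integral over the density ratio in the continuous case. It measures
how much the target's distribution *changes* when the source observation is
added to the context — the number of extra bits needed to describe the
updated state of expectation in terms of the previous one. It is
non-negative, and in the discrete case bounded above by the information
content of the source given the context; averaging over both source and
context recovers the conditional mutual information $I(A;B\mid C)$.

Two structural identities tie it back to the classical signals (and are
verified by brute force in the test suite): the expected gap between
conditional information content and contrast,
$\mathbb{E}_{B,C}[\ell(B \mid C) - I(A;B \mid C)]$, equals the conditional
entropy $H(B \mid A, C)$, and reaches its maximum $H(B)$ exactly when the
source is independent of target and context.

The choice of the relative-entropy form costs additivity: the information
from a split source does not decompose into chained terms, and the suite
checks this non-additivity on a constructed joint. Base-2 logarithms (bits)
are the package default everywhere, switchable to nats per call; all internal
computation is in nats with a single conversion at the boundary.

## Temporal variants

Partitioning a process around a chosen moment into past $X$, present $Y$ and
future $Z$, and assigning these regimes to (target, source, context), yields
six variants:

| variant | expression | reading |
|---|---|---|
| predictive | $I(Z; y \mid x)$ | foresight gained from the present |
| connective | $I(Z; x \mid y)$ | memory needed beyond the present |
| reflective | $I(Y; z \mid x)$ | hindsight about the present from the future |
| b-predictive | $I(X; y \mid z)$ | predictive, against a fixed future |
| b-connective | $I(X; z \mid y)$ | connective, against a fixed future |
| b-reflective | $I(Y; x \mid z)$ | reflective, against a fixed future |

For any Markov process the present screens the past off from the future, so
the connective variants are *identically zero*; the closed forms return the
exact constant and the test suite confirms the zero against the definitional
joint. Backward variants are forward variants computed on the time-reversed
chain ($R = D_\pi P^\top D_\pi^{-1}$, or the reversed rate matrix), a duality
also checked explicitly.

## Closed forms and their oracles

Every closed-form path in the package is validated against a slower,
independent route:

* **DTMC / CTMC.** With a column-stochastic transition matrix $P$ (columns
  sum to 1; `P[j, k]` is the probability of moving *to* `j` *from* `k`) and
  stationary $\pi$, the $(j,k)$-step variants are sums over one-step kernels
  $P^j, P^k, P^{j+k}$ (powers by repeated squaring), or matrix exponentials
  $e^{uQ}, e^{vQ}, e^{(u+v)Q}$ in continuous time; backward variants use the
  reversed matrices. `markov_joint()` assembles the exact three-way joint
  of the window from $\pi$ and the kernels, and `contrast_from_joint()` — a
  direct triple-normalised sum — must agree to $10^{-10}$ absolute for every
  variant. Degenerate conditioning (a zero-probability path) is an explicit
  error, not a NaN.
* **Gaussian processes.** `gaussian_contrast()` conditions the window's
  multivariate Gaussian twice (standard block formulas) and takes the
  Gaussian KL divergence. For one-dimensional regimes this reduces
  algebraically to a scalar expression in the two conditional means and
  variances, which the tests evaluate independently; multivariate cases are
  checked against the seeded Monte-Carlo estimator
  (`mc_contrast_continuous`, sample mean of log-density ratios with its
  plain $s/\sqrt{n}$ standard error) within three standard errors at
  $n = 10^5$. Affine re-description of all coordinates ($s \mapsto as + b$)
  must leave values unchanged within $10^{-9}$ — the coordinate-invariance
  property that motivates the measure.

## Estimation

* `estimate_dtmc` pools transition counts over all corpus sequences (never
  across sequence boundaries) with optional additive smoothing; a state with
  no observed departures and no pseudocount is an error because its column
  is undefined.
* `estimate_ctmc` uses the standard MLE — jumps over dwell time per column —
  with consecutive repeats merged into one dwell (a continuous-time chain
  has no self-jumps). The estimator was not prescribed beyond "maximum
  likelihood", so the canonical one is used.
* For chains estimated from short or degenerate data the stationary vector
  may not exist (absorbing or periodic structure); model constructors then
  warn and carry `pi = NULL`, and every quantity that needs the stationary
  distribution errors explicitly rather than silently renormalising.
* `estimate_stationary_gp` pools the mean over all values and estimates the
  autocovariance from centred lagged products within sequences. The default
  is the biased ($1/N$) estimator because it favours positive semi-definite
  Toeplitz windows; the unbiased per-lag version is a flag. The
  continuous-time autocovariance is a least-squares polynomial in the lag
  magnitude (`fit_continuous_autocov`, default degree 10, the lag axis
  scaled to $[0,1]$ for conditioning), valid only on the fitted domain —
  evaluation outside $[0, t_{\max}]$ is an error. Neither the bias choice
  nor the degree is canonical; both are parameters with these defaults.

**Positive-definiteness repair.** A fitted autocovariance need not induce
positive-definite Toeplitz windows. Window covariances are symmetrised, then
jittered starting at $10^{-10}\gamma(0)$ doubling at most 20 times, then (with
a warning) eigenvalue-clipped at $10^{-12}\gamma(0)$. In discrete time the
autocovariance is taken as zero beyond the last stored lag, which is exact
for moving-average-type processes and an approximation otherwise.

## Profiles

`markov_profile` and `gp_profile` trace a variant along a realised sequence.
In discrete time, one value per event that has both a $j$-step past and a
$k$-step future neighbour (so $N - j - k$ rows), each equal to the
corresponding single-point call; the Gaussian discrete profile uses extended
regimes $X = \{S_{n-j},\dots,S_{n-1}\}$, $Y = S_n$,
$Z = \{S_{n+1},\dots,S_{n+k}\}$ on the Toeplitz window. In continuous time
the profile is a curve on a user-chosen grid (`grid_step`, a free resolution
parameter) between consecutive onsets: for the predictive scheme the past
and present sit at the two most recent onsets and the future sweeps the
current gap; for the reflective scheme the flanking onsets hold past and
future while the present sweeps between; backward-predictive mirrors this
with the swept past point in the preceding gap.

## The PPM comparison model

To relate contrast information to the classical signals on symbolic data,
the package ships a variable-order PPM model: escape method C
(escape mass $d/(n+d)$ for $d$ distinct continuations among $n$ counts),
backoff smoothing without update exclusion, trained once on a corpus and then
applied statically. The escaped mass at each order is spread over the *full*
alphabet's next-lower-order distribution, bottoming out at uniform — the
construction implied by the hand-worked escape cascade (for "abracadabra" at
order 1, $p(\mathrm{b}\mid\mathrm{a}) = 2/7$ plus b's share of the $3/7$
escape mass through orders 0 and $-1$), and the only backoff that sums to
one without renormalisation. A consequence worth noting: every prediction is
strictly positive, so PPM information content and contrast are always finite.

PPM natively predicts the present from the past; it has no joint model over
futures. The forward predictive contrast here therefore uses a *point*
future ($k = 1$) and constructs the future-given-past distribution by
marginalising over a hypothetical present:
$p(z \mid x) = \sum_{y'} p(y' \mid x)\, p(z \mid x, y')$, contexts truncated
to the order bound. This is a documented modelling choice, not a canonical
one — published correlation tables built on a differently-assembled joint
would not be expected to reproduce exactly even on the same corpus, which is
one reason (besides the corpus being external) that the package validates
the correlation machinery against direct formula evaluation rather than
against printed corpus-level values. Correlations pool events across the
corpus by default; per-sequence use is just `correlate_profiles` on
per-sequence columns.

On data *generated by* a first-order Markov chain, the order-1 PPM
predictive-contrast profile converges to the exact chain profile as the
training corpus grows (smoothing mass vanishes as counts accumulate); the
suite checks a monotone shrinking mean absolute gap across corpus sizes 400,
3,200 and 25,600 symbols against a 120-event test sequence.

## What the synthetic generators emulate

All test fixtures are generated in code: seeded DTMC paths (stationary start,
column-wise sampling), CTMC jump chains with exponential dwells, and Gaussian
draws from the induced Toeplitz covariance. The stop-light chain (stay .95 /
switch .05) is the worked reference case; random ergodic chains use strictly
positive entries, so they probe the generic regime rather than boundary
cases with structural zeros. Recovery tests use problem sizes chosen for
tight-but-robust bounds: $10^5$ DTMC steps for an $L_\infty$ transition
error below .01, $3\times10^4$ CTMC jumps for per-rate relative error below
5% (at $10^4$ jumps that bound would be a one-sigma coin flip), and
length-3,000 Gaussian samples from an MA(2)-type autocovariance — exactly
zero beyond lag 2, hence exactly PSD under truncation — for absolute
autocovariance error below .2. Real musical corpora differ from these
fixtures in ways the tests deliberately do not model: non-stationarity,
structural zeros in transition support, heavy-tailed duration distributions,
and phrase structure. Passing tests certify the mathematics of the measure
and the estimators' consistency, not the adequacy of any particular model
for music.

## Numerical choices and limitations

* $0 \log 0 = 0$ throughout; joints are accepted and renormalised when their
  total is within $10^{-9}$ of one, rejected otherwise.
* Stationary distributions come from the eigen-decomposition (unit
  eigenvalue) with a residual check at $10^{-10}$ and a power-iteration
  fallback; irreducibility is checked as strong connectivity of the
  positive-support graph, aperiodicity as the absence of other unit-modulus
  eigenvalues.
* Matrix exponentials use scaling-and-squaring (`Matrix::expm`); matrix
  powers use repeated squaring.
* All randomness flows through explicit seeds (`with_seed` saves and
  restores the caller's RNG state); no function touches global RNG state.
* Higher-order Markov closed forms are out of scope (use the PPM module or
  alphabet augmentation); non-stationary chains and GPs, kernel learning,
  multiple-viewpoint combination by entropy weighting, and boundary-entropy
  segmentation are not implemented.

```{r example}
light <- dtmc_model(matrix(c(.95, .05, .05, .95), 2), c("RED", "GREEN"))
c(
  green_in_red = dtmc_contrast(light, "predictive", x = "RED", y = "GREEN"),
  red_in_red   = dtmc_contrast(light, "predictive", x = "RED", y = "RED")
)
```
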