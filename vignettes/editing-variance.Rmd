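---
title: "Quantifying cell-to-cell variance in RNA editing rates"
author: "editvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-to-cell variance in RNA editing rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editvar)
```

## Motivation and model

C-to-U RNA editing rates measured in bulk RNA-seq are population averages.
A moderately edited site may reflect uniform moderate editing in every
cell, or near-complete editing in a cellular subset. Distinguishing the
two requires single-cell data, but at a single base the per-cell read
depth `n_j` is small and capture is stochastic, so the observed per-cell
ratio `x_j / n_j` cannot be read off as that cell's editing rate.

`editvar` treats each site independently and models, for `J` cells,

$$x_j \mid p_j \sim \mathrm{Binomial}(n_j, p_j), \qquad
  p_j \mid v \sim \mathrm{Beta}(\text{mean} = \hat p,\ \text{variance} = v),$$

with the beta layer in its mean/variance parametrization and the mean
fixed at the bulk estimator $\hat p = x/n$. Because the bulk experiment
pools a very large number of cells (on the order of $10^5$ or more), the
uncertainty in $\hat p$ is negligible next to everything else, and fixing
it keeps the variance $v$ — the quantity of scientific interest — as the
single top-level parameter. Its support $[0, \hat p(1-\hat p)]$ is
interpretable end to end: $v = 0$ is "all cells edit identically", the
upper bound is "cells are all-or-nothing".

Two representational choices matter downstream:

* **`v = 0` is an explicit degenerate case.** The beta shapes
  $\alpha = m s$, $\beta = (1-m)s$ with $s = m(1-m)/v - 1$ diverge as
  $v \to 0$, so `beta_shapes()` refuses `v = 0` with a typed condition and
  every caller branches explicitly (the beta-binomial pmf falls back to
  the binomial; predictive draws return $\hat p$ itself).
* **Degenerate bulk estimates are clamped.** A bulk pair with $x = 0$ or
  $x = n$ gives $\hat p \in \{0, 1\}$, which cannot serve as a beta mean.
  `clamp_rate()` moves it to $[1/(2n), 1 - 1/(2n)]$ — half a read at the
  data's own resolution. How such sites were treated originally is not
  documented; this rule is this package's choice.

The beta-binomial pmf is computed in log space via `lbeta`/`lchoose`, so
coverages of several hundred reads pose no underflow risk.

## The penalized-complexity prior on the variance

The prior encodes a preference for the simpler explanation: no
variability. Complexity of the flexible model at variance $v$ is measured
by the distance $d(v) = \sqrt{2\,\mathrm{KL}(v)}$ to the base model
$v = 0$, an exponential distribution $\lambda e^{-\lambda d}$ is placed on
that distance, and $\lambda$ is calibrated from a tail condition
$P[v > v_L] = \alpha$ (defaults $v_L = 0.142$, $\alpha = 0.01$ — a
conservative prior assuming little variability).

Three numerical decisions were genuinely open:

* **Level of the KL divergence.** At the latent level, a continuous beta
  against the point mass at $\hat p$ has infinite divergence for every
  $v > 0$, which cannot be calibrated. The divergence is therefore taken
  between the *observable* read-count laws — beta-binomial versus binomial
  — at a reference coverage `n_ref`, computed as the exact finite sum over
  `0..n_ref`. The default `n_ref = 20` is the coverage the model
  recommends per cell; it can be set per site (e.g. the median observed
  `n_j`). At the support boundary $v = \hat p(1-\hat p)$ the beta layer
  degenerates to a two-point mixture and a closed form is used (for
  $p = 0.5$, coverage $n$: $(n-1)\log 2$ nats).
* **Truncation.** On a bounded variance support $d$ is bounded by
  $d_{\max} = d(v_{\max})$, so an untruncated exponential would place
  prior mass on unreachable distances and the induced prior on $v$ would
  not integrate to one. The exponential is truncated to $[0, d_{\max}]$
  and renormalized; the calibration equation
  $(e^{-\lambda d_L} - e^{-\lambda d_{\max}})/(1 - e^{-\lambda d_{\max}})
  = \alpha$ is solved by bracketed root finding and reduces to
  $\lambda = -\log\alpha / d(v_L)$ when truncation is negligible.
* **Derivative of the distance.** The induced density on $v$ is
  $\lambda e^{-\lambda d(v)} d'(v)$ (renormalized); $d'$ has no closed
  form and is computed by central finite differences with step
  $\min(10^{-5}, v/10, (v_{\max}-v)/10)$, shrinking near the boundaries
  where the distance flattens or steepens.

The test suite verifies that the calibrated prior integrates to one, puts
$1 - \alpha$ of its mass below $v_L$, and that $d$ is monotone with
$d(0) = 0$ across a grid of bulk means and reference coverages.

## Posterior computation

The sampler is Metropolis-within-Gibbs with the conjugacy the hierarchy
provides:

* $p_j \mid v, x_j \sim \mathrm{Beta}(\alpha(v) + x_j,\ \beta(v) + n_j -
  x_j)$, drawn exactly for all cells at once. Cells with $n_j = 0$ are
  retained — they contribute no likelihood and their rate is drawn from
  the beta layer itself — which keeps cell indexing stable and matches
  the model's factorization.
* $v \mid \{p_j\}$ has no standard form. It is updated by Gaussian
  random-walk Metropolis on $u = \mathrm{logit}(v / v_{\max})$, which
  respects the bounded support without rejection at the edges; the
  log-Jacobian $\log v + \log(v_{\max} - v)$ enters the acceptance ratio.
  The step size adapts every 50 iterations during burn-in towards an
  acceptance rate of 0.25–0.45 and is frozen afterwards, so the retained
  chain is a fixed-kernel Markov chain.

Defaults are 20,000 iterations with 5,000 burn-in — a per-site run takes
a few seconds — and the seed is a required argument: identical seed and
settings give bitwise-identical draws. Convergence checking is
deliberately lightweight (acceptance rate plus seed-replicate agreement);
multi-chain diagnostics are out of scope for a single bounded parameter
with conjugate nuisance updates.

Summaries:

* **HPD intervals** are computed as the shortest window of
  $\lceil 0.95 N \rceil$ sorted draws — exact for unimodal posteriors,
  which is what this model produces.
* **"Excludes zero"** is operationalized as the HPD lower bound clearing
  $\delta = 10^{-3}$ on the variance scale, since a continuous sample
  never literally contains 0.
* **Marginal editing rates**: one draw
  $p_{\text{new}} \sim \mathrm{Beta}(\hat p, v)$ per retained $v$ draw —
  the predictive editing rate of an unobserved cell.
* **Density estimation and modes** on bounded supports use beta kernels:
  each draw $d_i$ contributes $\mathrm{Beta}(d_i/b + 1, (1-d_i)/b + 1)$,
  keeping all mass inside $[0, 1]$. The bandwidth defaults to
  $\max(10^{-3}, \mathrm{sd} \cdot N^{-2/5})$; posterior modes (e.g.
  `v_mode` in summaries) are the KDE maximum on a 512-point grid, with
  variance draws rescaled by $v_{\max}$ first.

## What the simulator emulates

`simulate_scenario()` reproduces the artificial data sets used to
validate the model: per-cell rates are drawn by choosing a rate region by
weight and then uniformly within it (uniformity is the minimal assumption
consistent with "rates sampled from a region"), and edited-read counts
are the *deterministic* rounding of rate × coverage, nudged by one read
if rounding left the region (when an integer ratio inside it exists).
Counts are deliberately not binomial draws: the scenarios fix effective
rates inside their regions, and the binomial layer is what the model
itself supplies during inference. The bulk pair aggregates a separate
large population (default $10^5$ cells, following the picture of the bulk
as a draw of many individual transcript copies from the whole population,
with an option to reduce read depth or population size), then draws the
bulk count binomially at $10^4$ reads so estimator noise is negligible
against region widths.

The preset catalogue covers: maximal-variance data (0–5% ∪ 95–100%), the
homogeneous control (45–55%), coverage sweeps {100, 50, 20, 10} at
J = 20, cell-number sweeps {50, 20, 10, 5} at coverage 20, and the
physiological scenarios — uniform 0–20% (bulk mean 10%), uniform 20–50%
(bulk mean 35%), and the bimodal 5–15% ∪ 40–50% data. For the bimodal
presets the stated bulk means (10% "within a region" vs. 35% "between the
regions") are not both reachable as mixture means of equally weighted
cells, so `scenario_config()` accepts a `bulk_mean` override used by
those two presets: cells are drawn equally from both regions and the bulk
pair is constructed at the stated mean. This isolates exactly the effect
being probed — where the bulk mean sits relative to the modes.

Passing tests on these scenarios show the model behaves as designed on
data matching its own assumptions (independent cells, a single site,
rates constant within a cell, unbiased read sampling). They do not
certify behaviour under features real single-cell data add: capture
dropout beyond what low $n_j$ encodes, transcript-level correlation
between sites, PCR duplicates, or mapping artefacts.

## The detection statistic

The bulk wild-type vs. knockout caller compares per-site base-count
vectors $(A, T, G, C)$ by their angle
$\arccos(\mathbf{wt}\cdot\mathbf{ko}/|\mathbf{wt}||\mathbf{ko}|)$ —
scale-invariant, so expression differences between samples cancel. A site
is called when count-level QC passes (≥ 5 wild-type reads, ≥ 2 edit
reads, no second non-reference base at ≥ 2 reads, no edit signal in the
knockout), the wild-type vector magnitude is at least 15, the angle at
least 0.11 radians, and the site avoids SNP and repeat intervals and a
±4 bp window around splice junctions. At coverage 20 against a pure-
reference knockout, the 0.11-radian threshold switches on at exactly 2 of
20 edited reads — a 10% editing rate.

Decisions worth recording:

* **Magnitude is the Euclidean norm.** "Magnitude of a vector" is read as
  its norm; one consequence, verified by enumeration in the tests, is
  that at coverage 20 the admitted edited-read counts are
  {2..6} ∪ {14..20}: a balanced two-base vector has norm
  $\sqrt{x^2 + (20-x)^2} < 15$ for mid-range $x$. Interpreting magnitude
  as total coverage would instead admit all of {2..20}; users wanting
  that behaviour can lower `min_wt_norm`.
* **Strand handling.** C-to-U editing is transcript-stranded: minus-strand
  sites appear as genomic G→A and are handled by complementation, and the
  tests verify a minus-strand site calls identically to its plus-strand
  mirror image.
* **"Multiple types of transitions"** is operationalized as any second
  non-reference base reaching the same ≥ 2-read support threshold as the
  edit itself; the original cutoff is not documented.
* **Coordinates** are 1-based in all site tables (matching the
  `chrX:9436449` convention); BED exclusion tracks are 0-based half-open
  and converted on import by `rtracklayer`.
* The caller consumes per-site count tables, so the statistic is testable
  without alignment machinery; `filter_read()` expresses the read-level
  rules (no indels, no edits in the terminal 2 bp) for upstream adapters.
  Read alignment, duplicate removal, and BLAT remapping checks are out of
  scope and assumed done upstream.

## Problem sizes and runtime choices

Unit and property tests run the sampler at 3,000–4,000 iterations with
500 burn-in, which mixes adequately for this one-parameter target; the
low-variance recovery check and the acceptance script use the full
default 20,000/5,000 chains. Parameter-recovery coverage (95% HPD
covering the generating $v$ in ≥ 80% of 25 replicates per setting) is
evaluated at $v_{\text{true}} \in \{0.005, 0.05, 0.12\}$ with J = 20
cells at coverage 20 — small-J coverage of an HPD interval is not exactly
95%, hence the 80% bar. The Monte-Carlo oracle for the beta-binomial pmf
uses $10^6$ compound draws; beta-kernel KDE consistency is checked on
$10^5$ draws from a known beta density.

## Limitations

* One site at a time: no sharing of information across sites, no
  modelling of inter-site correlation within a transcript.
* $\hat p$ fixed: appropriate for deep bulk data; with a shallow bulk
  sample the model understates uncertainty.
* The exact chain configuration of the original analysis is not
  recoverable, so agreement is distributional (posterior shapes,
  HPD behaviour), never draw-level.
* The caller's thresholds are tuned for deduplicated bulk data at
  moderate depth; on very deep data the fixed ≥ 2-read edit support
  becomes permissive and the norm threshold immaterial.
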