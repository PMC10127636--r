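---
title: "Why many antagonists change microbial communities less than one: the model behind antagosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Why many antagonists change microbial communities less than one}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antagosim)
```

## The question

Phages, plasmids and other mobile genetic elements (MGEs) impose growth
costs on their bacterial hosts, and those costs differ between host taxa.
If a community faces only one antagonist, the taxon it burdens most is
pushed down and composition shifts. But real communities face many
antagonists at once, each with its own pattern of costs. If those patterns
are not perfectly correlated, the *net* burden each taxon carries is a sum
of many independent draws — and sums of independent draws concentrate.
The prediction: the more antagonists a community hosts, the more their
differential effects cancel, and the *less* its composition deviates from
the antagonist-free state. `antagosim` implements the population-dynamic
model behind that prediction and the Monte-Carlo experiment that tests it.

## The model

Dynamics are competitive Lotka–Volterra for all $N = n + m$ species
(focal bacteria plus antagonists):

$$\frac{dx_i}{dt} = r_i x_i \Big(1 - \sum_{j=1}^{N} \alpha_{ij} x_j\Big),$$

where $\alpha_{ij}$ is the per-capita effect of species $j$ on species
$i$'s growth bracket ($\alpha$ rows are "affected", columns "acting" —
the convention the sum fixes). The random interaction matrix has four
blocks:

* **focal–focal**: diagonal exactly 1; off-diagonals i.i.d.
  $\mathrm{Uniform}(0, A/n)$. $A$ tunes overall interspecific
  competition; dividing by $n$ keeps total competitive load comparable
  across community sizes.
* **antagonist impacts on focal species** ($n \times m$): i.i.d.
  half-normal $N^+(0, \sigma)$ — always a cost, never a benefit.
* **focal effects on antagonists**: all 0. Antagonist densities do not
  respond to which focal species are present (a deliberately conservative
  caricature of generalist pressure; no kill-the-winner feedback).
* **antagonist–antagonist** (including self): all 1, so the antagonist
  guild behaves like one logistic unit whose total density settles at 1.

All growth rates $r_i$ are i.i.d. half-normal $N^+(0, 1)$, strictly
positive (exact floating-point zeros are resampled). The model prescribes
no separate rule for antagonist growth rates, so they share the focal
distribution.

## Why cancellation follows

Each focal species $i$ carries a combined antagonist burden
$\beta_i = \sum_{k=1}^m \theta_{ik}$ with i.i.d. positive
$\theta \sim N^+(0,\sigma)$. Then $E(\beta) = E(\theta)\,m$ and
$\mathrm{Var}(\beta) = \sigma_\theta^2\, m$, so

$$\mathrm{CV}(\beta) = \frac{\sqrt{\sigma_\theta^2 m}}{E(\theta)\, m}
  = \sqrt{\tfrac{\pi}{2} - 1}\; \frac{1}{\sqrt{m}},$$

independent of $\sigma$ for the half-normal (its shape constant
$\mathrm{Var}/E^2 = \pi/2 - 1$ is scale-free). As $m$ grows, the burdens
$\beta_1, \dots, \beta_n$ become relatively more similar across focal
species, and a near-uniform burden shifts everyone's bracket almost
equally — composition barely moves. `cv_combined_effect()` implements
the closed form; the acceptance suite checks it against Monte-Carlo sums
of half-normal draws within 2%.

## The *in silico* experiment

`paired_run()` draws one focal community (its interaction block and its
growth rates), then simulates it **twice from identical initial
conditions**: once with $m$ antagonists appended, once without. The two
focal equilibria are converted to relative abundances and compared with

* **Bray–Curtis dissimilarity** $1 - \sum_i \min(p_i, q_i)$ (equal to
  half the $L_1$ distance on normalized vectors), and
* **Kendall rank correlation** over all $n(n-1)/2$ species pairs, ties
  counting toward neither concordant nor discordant.

We read "the corresponding relative abundances where m = 0" as the
*matched* baseline — the same focal draw solved without its antagonists —
because per-run dissimilarities only make sense between matched
communities. An independent-baseline mode
(`paired_run(..., pairing = "independent")`) is available for sensitivity
analysis.

`run_sweep()` repeats this over a grid. The published experiment covers
$n = 2, 4, \ldots, 20$; $m = 1, \ldots, 10$; $\sigma = 0.1, \ldots, 1$;
$A = 0.1, \ldots, 1$ (both in steps of 0.1 — the source's "0.1, 0.1, (…),
1" for $\sigma$ can only be a step-size typo) at 100,000 replicates per
tile. That is a cluster-scale budget; the package defaults to a desk
profile of 2,000 replicates per tile, which is the identical estimator
with wider confidence bands, and the acceptance suite checks direction,
not magnitude, accordingly.

### Kendall normalization

The source formula divides $(n_c - n_d)$ by $n$, the species count. That
quantity exceeds 1 whenever more than $n$ pairs are concordant (any
$n \ge 4$ with full concordance), while the published heat maps live on a
scale bounded by 1 — so the default here is standard tau-a, dividing by
the pair count $n(n-1)/2$. The printed variant is kept as
`kendall_rank(..., variant = "paper_literal")` for exact replication
attempts; for $n = 3$ the two coincide.

## Numerical choices

* **Integrator.** An adaptive explicit Runge–Kutta 5(4) scheme
  (Dormand–Prince pair with FSAL), written in C++ for the sweep's inner
  loop. The source used the Tsitouras 5/4 pair; both are fifth-order
  adaptive schemes and the equilibrium readout is tableau-insensitive,
  which the fixed-step Euler oracle (`integrate_euler()`, plain R,
  sharing no code with the production path) verifies within $10^{-3}$.
* **Horizon.** "1,000 time steps" is ambiguous for an adaptive solver;
  we integrate over a fixed horizon $t_{\mathrm{end}} = 1000$ time units
  and report a convergence flag (derivative infinity-norm below
  $10^{-6}$ at $t_{\mathrm{end}}$) rather than assuming convergence.
* **Initial conditions.** Unstated in the source; every species starts
  at density 0.1 — symmetric, strictly positive, below carrying
  capacity. Configurable (`integration_settings(x0 = )`) and logged by
  the CLI.
* **Tolerances.** `rel_tol = abs_tol = 1e-8`, readout floor
  $10^{-12}$: all far below the composition differences the metrics
  measure.
* **Positivity.** Negative components produced by floating-point error
  are clipped to zero on step acceptance. Extinction is absorbing in the
  model, so the clip is exact.
* **A solver artifact worth knowing.** A species whose growth bracket is
  strongly negative decays exponentially, but once its density falls to
  the absolute-tolerance scale ($\sim 10^{-8}$) the error controller
  stops resolving it and it can "park" there instead of reaching the
  $10^{-12}$ floor. Such species contribute $\sim 10^{-8}$ to relative
  abundances — invisible to Bray–Curtis, and a source of noise only in
  the ranks of effectively extinct species. Consequently fully degenerate
  replicates (all focal species below the floor) are essentially absent
  under default settings; raising `readout_floor` above the tolerance
  scale recovers strict extinction accounting, and degenerate replicates
  are always counted per tile, never silently dropped.
* **Seeding.** One root seed per sweep is split by a counter-based
  splitmix64 mixer into an independent stream per (tile, replicate), so
  results are reproducible byte-for-byte and independent of execution
  order. The generator (scrambled `mt19937_64` + Box–Muller) is fully
  specified, hence platform-independent; seeds crossing the R boundary
  are kept below $2^{53}$.

## What the synthetic world does and does not establish

The generator *is* the stated model: uniform competitive links, purely
antagonistic half-normal impacts, antagonists insensitive to focal
composition, no evolution of interaction strengths, no demographic noise.
A green directional test establishes that *within this world* increasing
$m$ shrinks compositional change (smaller Bray–Curtis, higher Kendall)
and increasing $A$ amplifies dissimilarity. It does not establish
anything about mutualistic MGEs, kill-the-winner feedbacks, or transient
(pre-equilibrium) dynamics, all of which are outside the model by
construction.

The directional acceptance checks use a trend criterion designed once,
before measurement: a sequence of tile means "trends" if its endpoints
move in the claimed direction and at least 80% of all ordered pairs do —
a Kendall-style concordance rule that tolerates Monte-Carlo wobble
between adjacent, nearly equal means without letting a non-monotone
sequence pass (`trend_holds()`).

## Diversity utilities

`shannon_diversity()` computes $H = -\sum_{p_i > 0} p_i \log p_i$
(natural log; the evenness ratio is base-invariant) and `evenness()`
Pielou's $J = H / \log S$, clamped at its mathematical upper bound 1 to
absorb $10^{-16}$-scale rounding. These summarize single compositions,
complementing the two between-community metrics.

## Known limitations

* The full published grid at 100,000 replicates per tile ($10^8$ paired
  integrations) is out of desk-scale reach; `full_grid()` constructs it,
  but expect hours, not minutes, at that setting.
* The explicit solver has no stiff fallback; a replicate that exhausts
  `max_steps` is recorded as a failure and counted with the degenerate
  replicates of its tile.
* Only the half-normal impact distribution is built in, matching the
  simulations; the CV derivation holds for any positive finite-variance
  distribution, and `half_normal_moments()` marks the seam where another
  could be added.
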