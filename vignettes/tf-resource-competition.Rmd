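---
title: "Transcription under a shared transcription-factor budget: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcription under a shared transcription-factor budget: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfshare)
```

## The model

A cell carries a fixed, conserved number $N_\mathrm{TF}$ of copies of one
transcription factor (TF). These are shared between $N_P$ identical promoter
copies, each with a single TF binding site, and $N_C$ competitor ("decoy")
sites that bind the TF without driving expression of the gene of interest.
Writing $n$ for the number of TF-bound promoters, $c$ for the number of bound
competitor sites and $F = N_\mathrm{TF} - n - c$ for the free pool, the
elementary reactions and their propensities are

| reaction                 | propensity                          |
|--------------------------|-------------------------------------|
| TF binds promoter $i$    | $k_\mathrm{on} F (1 - s_i)$         |
| TF leaves promoter $i$   | $k_\mathrm{off} s_i$                |
| TF binds a competitor    | $k_\mathrm{on}^C F (N_C - c)$       |
| TF leaves a competitor   | $k_\mathrm{off}^C c$                |
| transcription at $i$     | activator: $r s_i + r_0 (1 - s_i)$; repressor: $r (1 - s_i)$ |
| decay of one mRNA at $i$ | $\gamma m_i$                        |

with $s_i \in \{0, 1\}$ the occupancy of promoter $i$ and $m_i$ the mRNA pool
attributed to promoter $i$. Copy numbers are exact integers; all rates are in
s$^{-1}$ and time in seconds. Aggregated over promoters the binding propensity
is $k_\mathrm{on} (N_\mathrm{TF} - n - c)(N_P - n)$, which at $c = 0$ is the
generator of the master equation for the joint law $P(n, m, t)$. For a single
promoter the model reduces to the classic telegraph (ON--OFF) promoter.

The per-promoter representation (rather than the aggregate $(n, m)$) is
statistically equivalent for identical promoters but is required for the
two-promoter correlation analysis; mRNAs are attributed to the promoter that
produced them, which leaves the total-mRNA law untouched because decay is
linear.

Default rates, returned by `ecoli_rates()`, are realistic for bacterial
promoters: $k_\mathrm{on} = 0.0027$, $k_\mathrm{off} = 0.0023$, $r = 0.33$,
$\gamma = 0.011$ (all s$^{-1}$), so a permanently active promoter holds
$r/\gamma = 30$ mRNAs on average, with mRNA lifetime $1/\gamma \approx 91$ s.
Competitor rates default to the promoter rates; both can be overridden. The
basal rate $r_0$ defaults to zero (typical for strongly activated bacterial
promoters) and is only meaningful for activators.

## Exact machinery

Three independent routes to the steady state are implemented, which
cross-validate each other in the test suite:

1. **Stochastic simulation** (`simulate_trajectory()`,
   `sample_population()`). The Gillespie direct method, implemented in C++
   with a fixed channel layout so a given random stream always maps to the
   same event sequence. Each replicate cell runs on its own counter-seeded
   xoshiro256++ stream derived from the master seed and the replicate index,
   so results are bit-reproducible and replicate $k$ can be regenerated in
   isolation. The default population snapshot time (burn-in) is $10/\gamma
   \approx 909$ s. Note that the mRNA lifetime is not always the slowest
   timescale: promoter occupancy relaxes at $k_\mathrm{on}
   N_\mathrm{TF}/\ldots + k_\mathrm{off} \sim 0.005$ s$^{-1}$ at the default
   rates, i.e. over $\sim$200 s. Experiments that need tight stationarity
   (e.g. distribution-level comparisons against the exact solver) therefore
   pass an explicit burn-in of a few thousand seconds; the
   initial-condition-independence test demonstrates the protocol.

2. **Truncated master-equation solve** (`cme_steady_state()`). The stationary
   distribution on the aggregate $(n, c, m)$ lattice, $m \le m_\mathrm{max}$,
   found by replacing one balance equation of the sparse generator with the
   normalization row and solving directly (Matrix package). State spaces here
   stay below $\sim 10^4$--$10^5$ states, where a direct sparse solve is both
   fast and accurate. The truncation is reflecting (transcription is dropped
   at the boundary); $m_\mathrm{max}$ starts at $N_P r/\gamma + 10\sqrt{N_P
   r/\gamma}$ and doubles until the boundary mass falls below `tol` (default
   $10^{-8}$). The aggregate lattice is exact for identical promoters.

3. **Markov-modulated moment systems** (`exact_moments()`,
   `cme_promoter_correlation()`). Conditional on the finite binding chain,
   each mRNA pool is a linear birth--death process, so its conditional first
   and second moments satisfy closed finite linear systems on the occupancy
   states. This gives mRNA means, variances and the two-promoter covariance
   *exactly*, with no truncation at all, at the cost of only a small dense
   solve. The two-promoter correlation uses the per-promoter occupancy chain
   $(s_1, s_2, c)$; everything else uses the aggregate $(n, c)$ chain.

The binding subsystem on its own is a reversible finite chain whose
stationary law has the closed product form
$P(n, c) \propto \binom{N_P}{n} \binom{N_C}{c}
\frac{N_\mathrm{TF}!}{(N_\mathrm{TF}-n-c)!}
(k_\mathrm{on}/k_\mathrm{off})^n (k^C_\mathrm{on}/k^C_\mathrm{off})^c$;
`occupancy_distribution()` computes the linear-solve answer and verifies it
against this closed form to $10^{-10}$ on every call.

## Closed forms and the master curve

For one promoter, no competitors and zero basal rate, the steady-state mean
and variance have exact closed forms (`analytic_moments()`); with
$q = k_\mathrm{on} N_\mathrm{TF}$ and $b = r/\gamma$, the activator mean is
$b\,q/(q + k_\mathrm{off})$ with Fano factor
$1 + k_\mathrm{off} r / ((q + k_\mathrm{off})(\gamma + q + k_\mathrm{off}))$,
and the repressor case swaps the roles of $q$ and $k_\mathrm{off}$ in the
mean and numerator. Eliminating $q$ between the mean and the variance yields
the variance-versus-mean *master curve* (`master_curve_variance()`), which by
construction involves only $r$, $\gamma$ and $k_\mathrm{off}$.

The master-curve story for competitor sites deserves a precise statement,
because the package's exact solvers sharpen it. The premise is that
competitors only renormalize the TF pool seen by the promoter, i.e. enter
only through an effective binding rate; the variance-versus-mean relation of
a single target promoter should then be untouched by $N_C$. Two independent
exact routes (the truncated CME solve and the truncation-free modulated
moments, which agree to machine precision) show that this collapse is *not*
mathematically exact: the free-pool fluctuations make the promoter's OFF-time
distribution non-exponential, and the exact variance deviates from the curve
by up to a few percent in the least favourable regime tested (slow competitor
rates, TF count comparable to the site count). The deviation vanishes
rapidly as $N_\mathrm{TF}$ grows (order $10^{-6}$ relative by
$N_\mathrm{TF} = 50$ at $N_C = 10$) and is zero at $N_C = 0$ by construction.
Simulated scatter plots cannot resolve a ~2% systematic offset, which is why
the collapse looks perfect at simulation resolution. For two promoter copies
the deviation is several-fold larger still (tens of percent at
$N_\mathrm{TF} = 3$), so the qualitative contrast — near-collapse for one
promoter, clear failure for several — is real and is what the acceptance
checks quantify: `collapse_residuals()` reports
$|\mathrm{var}/N_P - \mathrm{curve}(\langle m\rangle/N_P)| /
\mathrm{curve}(\langle m\rangle/N_P)$ pointwise and its maximum.

A related sharpening applies to the variance/Fano peaks across a TF sweep at
$N_P = 10$ (exact engine, integer $N_\mathrm{TF}$ grid): the peaks sit at
parity to within one grid step, but the discrete argmax need not equal $N_P$
exactly — at the default rates the activator variance argmax is
$N_\mathrm{TF} = 11$ and the Fano argmax $N_\mathrm{TF} = 9$, with near-tie
margins below $0.1\%$ against the value at 10; the repressor variance peaks
exactly at 10 and its Fano peak falls clearly above parity. The package's own
tests therefore assert parity within one step (and strictly-above-parity for
the repressor Fano), while the acceptance checks record the literal argmax.

## Moment closure

For several promoters the moment hierarchy does not close: the equation for
the cross moment $\langle n m \rangle$ involves $\langle n^2 m \rangle$.
`closure_moments()` takes the occupancy-marginal moments from the exact
finite birth--death chain (always available) and closes the single remaining
term at second order by projecting $n^2$ onto $n$:
$\langle n^2 m\rangle \approx \langle n^2\rangle\langle m\rangle +
\beta\,\mathrm{cov}(n, m)$ with
$\beta = \mathrm{cov}(n^2, n)/\mathrm{var}(n)$. This scheme was chosen over
plain third-central-cumulant neglect because it is *exact* at $N_P = 1$
(where $n^2 = n$ gives $\beta = 1$), so the closure reduces to the closed
forms above, while remaining a genuine second-order approximation for
$N_P \ge 2$ — at $N_P = N_\mathrm{TF} = 10$ the closure mean is exact by
construction and the variance is within about 1% of the exact value. It is
an approximation and is flagged as such in the function documentation.

## Mode counting

mRNA counts are integers, so multimodality detection works directly on the
integer-support pmf rather than a kernel density (no bandwidth selection):
`count_modes()` applies a centered moving average (default window 5, partial
windows at the edges), finds local maxima with plateaus merged leftward —
boundary maxima count, since the $m = 0$ mode is biologically meaningful —
and keeps peaks whose topographic prominence is at least 5% (default) of the
highest smoothed value. The transition unimodal $\to$ multimodal as
competitor sites are added is insensitive to halving or doubling the window,
which the tests check.

The slow-switching intuition fixes where the modes sit: with two promoters
and three TFs at the default (slow) binding rates the exact distribution has
two modes near $r/\gamma$ and $2r/\gamma$ (one or two promoters
transcribing; the zero-complex state is too rare to leave a third peak).
With $k_\mathrm{on}$ raised to $0.027\ \mathrm{s}^{-1} > \gamma$ the
distribution is unimodal, and adding competitor sites at that fast binding
rate restores multimodality — including a mode at $m = 0$ — because
sequestration starves the free pool and re-lengthens the promoters'
unoccupied dwell times.

## Problem sizes and numerical choices

* Stationary solves: sparse LU with a normalization row; occupancy chains are
  solved densely (they have at most a few hundred states).
* CME truncation tolerance $10^{-8}$ boundary mass; moments converge to
  $\lesssim 10^{-7}$ absolute, verified by a Cauchy check in the tests.
* Population experiments use 10,000 cells (20,000 for distribution-level
  total-variation comparisons), burn-in 4,000–5,000 s for the comparisons
  against exact distributions, and 500–1,000 bootstrap resamples for
  standard errors. At 20,000 cells the sampling-noise floor of the total
  variation distance to the exact pmf is itself about 0.02 for these wide
  count distributions — distribution-level agreement cannot be certified
  much below that with this population size.
* TF sweeps for peak location use the exact engine; SSA peak location on a
  flat maximum is unreliable, and ties break toward smaller
  $N_\mathrm{TF}$.
* `fano()` returns `NaN` at zero mean rather than raising, so sweep tables
  can contain unexpressed conditions.
* Fold change divides by $N_P r / \gamma$ even when $r_0 > 0$.

## What the simulator does and does not emulate

The SSA emulates exactly the chemical master equation of this model: fixed
conserved TF count, identical promoters, one binding site each, no protein
layer, no cell growth, division, replication or extrinsic noise, and no TF
production/turnover. Passing tests therefore certify the mathematics of the
model, not biological completeness: in real cells gene dosage changes over
the cycle, TF numbers fluctuate, and decoy occupancy can be chromatinized or
cooperative. Within the model, every distribution-level claim is checked
against an exact solver, so simulation error is purely statistical.

## Worked example

```{r}
m <- do.call(tf_model, c(list(n_tf = 1), ecoli_rates()))
analytic_moments(m)
cme_moments(cme_steady_state(m))
```

```{r}
two <- do.call(tf_model, c(list(n_tf = 3, n_promoters = 2), ecoli_rates()))
count_modes(mrna_pmf(cme_steady_state(two)))
```
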