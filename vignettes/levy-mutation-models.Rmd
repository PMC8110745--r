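---
title: "Modeling mutation length spectra as stable Levy flights"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling mutation length spectra as stable Levy flights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(levymut)
```

## The model

Mutation accumulation along a surviving cell lineage is treated as a
Markov chain in mutation space, `X[i+1] = X[i] + delta[i]`: each
generation adds a random modification. `levymut` distinguishes two
components of `delta`:

* **single point mutations (SPMs / SNVs)** — length-1 events arriving as
  a Poisson stream with rate `p_spm` per generation (the Brownian
  component), and
* **large rearrangements (LRs)** — deletions, insertions, translocations,
  inversions, CNVs — arriving at rate `p_lr`, with lengths `l` drawn from
  a one-sided stable Levy law.

The mixture of many short steps with rare, arbitrarily long ones makes
the chain a Levy flight. The length law is the standardized density

$$L_\nu(y) = \frac{2}{\pi}\int_0^\infty e^{-q^\nu}\cos(q y)\,dq,
\qquad 0 < \nu \le 2,$$

used with an inverse-length scale $\alpha$ as $\alpha L_\nu(\alpha l)$.
It is the law of the absolute value of a symmetric stable variate with
characteristic function $e^{-|t|^\nu}$, so it is closed under summation
of independent components (generalized central limit theorem) — the
reason a single law can absorb the many distinct rearrangement
mechanisms. Its tail is scale-free: the density falls as
$1/y^{\nu+1}$ and the survival function $S_\nu(y)=\int_y^\infty L_\nu$
as $1/y^{\nu}$, with $1/\alpha$ the length above which the power law is
fully developed.

Key assumptions: events are independent across generations and types
(no selection, drift, clonal interference or population structure — the
simulator models the mutation *input* of one lineage, not the fate of
mutations in a population); rearrangement lengths are independent of
genomic position (positions are not modeled); time is discrete in
generations and events within a generation are exchangeable; Poisson
arrivals are used as the standard rare-event limit, the per-generation
Bernoulli alternative being indistinguishable at rates of order
$10^{-3}$.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `nu` | — | 1/2 (bacterial LR), 3/2 (human CNV) | tail index; survival falls as $l^{-\nu}$ |
| `alpha` | 1/bp | 1e-4 (bacterial), 1e-5 (CNV) | inverse length scale; $1/\alpha$ marks the onset of the scale-free tail |
| `p_spm` | /generation | 1.8e-3 | SPM rate of an *E. coli* lineage (clone-mean slope) |
| `p_lr` | /generation | 5e-4 | LR rate; a lower bound — sub-5 kbp events evade detection |
| `genome_length` | bp | 5e6 (2.4e8 germline) | physical cap on rearrangement lengths (rejection) |
| `mutator_generation`, `mutator_factor` | generation, fold | 27000, 100 | mutator genotype multiplying `p_spm` only |
| `f_detect`, `f_fix` | frequency | 0.04, 0.96 | population-frequency thresholds for detection and fixation |
| detection `floor` | bp | 5e3 | shortest reliably detected rearrangement |

The germline preset uses per-birth units: 60 SNV-like and 10
rearrangement-like events per birth with the $\nu = 3/2$,
$\alpha = 10^{-5}$ length law. (The ~60 SNVs are about five times *all*
other mutation classes combined, roughly 12 per birth; the preset's two
channels encode only the SNV and rearrangement rates.)

## Numerical evaluation of the stable density

No closed form exists for general $\nu$, so `levy_pdf()` and
`levy_survival()` combine three routes:

1. **Closed forms** for $\nu = 1$ (half-Cauchy, $L_1(y) =
   (2/\pi)/(1+y^2)$) and $\nu = 2$ (half-Gaussian,
   $L_2(y)=e^{-y^2/4}/\sqrt{\pi}$) — exact and fast.
2. **Oscillatory quadrature** elsewhere: the integrand is cut where its
   envelope falls below $10^{-16}$ ($q > Q$, $e^{-Q^\nu} = 10^{-16}$);
   the first, sign-constant segment is integrated adaptively because
   $e^{-q^\nu}$ has a derivative singularity at $q = 0$ for non-integer
   $\nu$ (a fixed Gauss rule there costs ~$10^{-4}$ absolute accuracy);
   subsequent half-periods of the cosine (or sine, for the survival
   identity $S_\nu(y) = 1 - (2/\pi)\int_0^\infty e^{-q^\nu}\sin(qy)/q\,dq$)
   use a 16-point Gauss rule and form an exactly alternating series.
   When the envelope decays too slowly to sum directly (small $\nu$,
   large $y$), the tail of that series is resummed by repeated averaging
   of partial sums (Euler / van Wijngaarden acceleration), capped at 480
   explicit segments.
3. **Tail series**
   $L_\nu(y) = (2/\pi)\sum_k (-1)^{k+1}\frac{\Gamma(k\nu+1)}{k!}
   \sin(k\pi\nu/2)\, y^{-k\nu-1}$ — convergent for $\nu < 1$,
   asymptotic (optimally truncated) for $\nu \ge 1$. The switch point is
   chosen per index as the smallest $y$ where series and quadrature
   agree to $10^{-6}$ relative and the series' truncation error is
   negligible, then cached for the session.

Against an independent stable-distribution implementation the combined
evaluator agrees to better than $10^{-7}$ absolute across
$\nu \in \{1/2, 3/2\}$ and $y \in [0, 100]$, and the density integrates
to 1 to better than $10^{-3}$ for all tested indices. Tiny negative
quadrature round-off (magnitude below $10^{-10}$) is clamped to zero;
anything more negative raises an error naming $y$ and $\nu$.

Sampling uses the Chambers–Mallows–Stuck construction of a symmetric
stable variate, takes absolute values, and divides by $\alpha$ — exact,
no inversion tables.

## Fitting the length spectrum

`build_integrated()` forms the integrated (rank-size) distribution
$N(\ge l)$ over *distinct* lengths; duplicates collapse into one point
carrying the full count so repeated sizes are not double-weighted, and
every distinct length carries equal weight in the fits (this matches
fitting the plotted points of a rank-size curve; weighting each event
instead would tilt the fit toward the shortest lengths).

Two fits operate in log10–log10 space, where the curves are straight and
the dynamic range (counts from 1 to $10^6$) is tame:

* `fit_powerlaw_tail()` — OLS of $\log_{10} N(\ge l)$ on $\log_{10} l$
  inside a window; the exponent is $\nu = -$slope via the identity
  $C\nu\int_l^\infty x^{-1-\nu}dx = C/l^\nu$. Default window
  5e3–1.7e6 bp (bacterial detection floor to just under the genome
  size); for CNV catalogs use `c(1e5, Inf)`, the regime $l > 1/\alpha$.
  Deliberately *not* a Clauset-style maximum-likelihood fit with
  $x_{min}$ selection: the windows here are fixed by experimental
  detection limits, and the rank-size OLS matches how such spectra are
  conventionally read.
* `fit_levy_scale()` — holds $\nu$ fixed and fits $\alpha$ in the
  integrated-Levy curve
  $f(l) = 1 + (N-1)\,[S_\nu(\alpha l) - S_\nu(\alpha l_{max})]\,/\,
  [S_\nu(\alpha l_{min}) - S_\nu(\alpha l_{max})]$, which by
  construction runs from $N$ at $l_{min}$ to 1 at $l_{max}$. The
  objective — log10 least squares over the distinct lengths — is this
  package's choice (a visual "good fit" criterion is not an algorithm);
  it is minimized by a 25-points-per-decade grid over
  $\alpha \in [10^{-8}, 10^{-1}]$ refined by golden-section search,
  which is robust to the objective's flat, occasionally multi-welled
  shape. The model curve is evaluated through a per-index log-log spline
  of $S_\nu$ (~$10^{-6}$ relative error, built once) rather than fresh
  quadratures per candidate $\alpha$; `levy_survival()` itself remains
  the accurate route, and the boundary identities hold to $10^{-9}$
  there.

On catalogs of $10^4$ events the scale fit recovers the generating
$\alpha$ well within a factor of 2 (typically within 10%), and the
power-law fit recovers a generating Pareto exponent within 0.1.
A caveat the synthetic runs make visible: fitting the *bacterial* window
(which starts at $\alpha l = 0.5$, before the tail is fully developed)
against true Levy-1/2 draws yields exponents around 0.40–0.45, not 0.50
— the finite-window bend is real and affects measured exponents in data
the same way.

## What the generators emulate — and what they do not

`synth_ltee_timeseries()` produces evolution-experiment-shaped series:
cumulative fixed counts, clone-mean counts
(`mean_mutations_in_clone()`: fixed plus the sum of polymorphic
frequencies, the additive expectation under independent sites) and LR
counts at sampled generations, with each SPM dressed with a population
frequency and classified by the 4%/96% thresholds. The frequency model
is pluggable and defaults to uniform on (0, 1) — a deliberate
placeholder, since no frequency spectrum is modeled. Consequences:
passing tests show threshold bookkeeping and Poisson thinning are
correct, *not* that the generator reproduces real fixation dynamics. In
real experiments beneficial mutations sweep to fixation, so the fixed
channel climbs at nearly the full SPM rate; under the uniform model it
climbs at only `p_spm * 0.04`. Selection, drift, clonal interference
and the daily-dilution demography are intentionally absent.

`synth_cnv_catalog()` draws from the truncated Levy law (rejection,
preserving the conditional law) and applies detection censoring — hard
(drop below the floor) or soft (detect with probability
$(l/\mathrm{floor})^\gamma$). Both true and observed catalogs are
returned so censoring effects stay testable; a hard floor below a fit
window provably cannot change the fit above it, and the tests assert
exactly that.

## Numerical and design choices, in brief

* Through-origin regression is the default rate estimator (the
  ancestral strain is the zero reference at generation 0); post-mutator
  segments are fitted with a free intercept since their counts do not
  extrapolate to zero. Default short-time window: generation 20,000,
  before the mutator complicates the series.
* Rearrangement lengths are continuous draws rounded *up* to whole bp
  (never 0), capped at the genome length by rejection resampling.
* Degenerate inputs error early with named messages: empty catalogs,
  lengths below 1 bp, windows with fewer than 3 points, all-equal
  lengths for the scale fit, changepoints outside the sampled span,
  frequencies outside (0, 1), infeasible truncation bounds.
* All stochastic entry points take a `seed` argument, restore the
  caller's RNG state, and are byte-reproducible for a fixed seed.
* Problem sizes used by the shipped analyses and tests: $10^4$–$10^5$
  events for spectrum fits, 40–200 replicate lineages for rate and
  mutator checks, 50,000-generation lineages — sizes at which the
  estimators' sampling error is a few percent and a full run stays
  interactive.

## Known limitations

* `p_lr`-style rate estimates inherit the detection floor: they are
  lower bounds, and reports should say so.
* The additive clone-mean expectation treats polymorphic sites
  independently; linkage in a clonal population violates this, so the
  channel is an order-of-magnitude reconstruction, not a likelihood.
* Only symmetric-stable-derived one-sided laws are implemented
  ($0 < \nu \le 2$); skewed and maximally-skewed stable families are out
  of scope.
* The asymptotic tail series is used from its auto-selected switch
  point; for indices very close to (but not equal to) 2 the series is
  weak and the quadrature branch simply extends further — correct but
  slower.
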