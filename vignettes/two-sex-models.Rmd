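---
title: "Two-sex stage-structured models with explicit mating: methods and design"
author: "bmmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sex stage-structured models with explicit mating: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmmr)
```

## The model

`bmmr` treats a sexually reproducing population as a continuous-time
stage-structured system in which three processes run simultaneously:
union formation (mating), birth, and life-cycle transitions. Each is a
rate matrix over the stage space `m1, m2, f1, f2, u1, ..., uh`; the
projection matrix is their average,

$$\frac{d\mathbf n}{dt} = \tfrac13\,(\mathbf T + \mathbf B + \mathbf U[\mathbf n])\,\mathbf n,$$

the continuous-time counterpart of running the three processes as a
periodic matrix product. Averaging over the number of processes keeps
rates additive; the growth rate $\lambda$ is therefore expressed on this
averaged-rate time scale, and all comparisons the package reports
(e.g. $\Delta\lambda$ under harvest) are internally consistent on that
scale.

Mating makes the model nonlinear: the union formation rate depends on
how many single adult males and females are present. Because it depends
only on their *relative* numbers, every entry of $\mathbf A$ is
homogeneous of degree 0 in $\mathbf n$ — the system is
frequency-dependent, and the composition $\mathbf p = \mathbf n /
\|\mathbf n\|_1$ obeys autonomous dynamics on the probability simplex,

$$\frac{d\mathbf p}{dt} = (\mathbf I_s - \mathbf p \mathbf 1^\top)\,\mathbf A[\mathbf p]\,\mathbf p .$$

These systems generically converge to an equilibrium composition
$\hat{\mathbf p}$ (the stable stage distribution), after which densities
grow exponentially at the Malthusian rate $\lambda$, the dominant
eigenvalue of $\mathbf A[\hat{\mathbf p}]$.

### Mating functions

The mating function family is the generalized weighted (Hölder) mean
$M = c[\beta f^{\alpha} + (1-\beta) m^{\alpha}]^{1/\alpha}$ with
$\beta \in [0,1]$, $\alpha < 0$. It is degree-1 homogeneous and vanishes
when either sex is absent — the two structural requirements on a two-sex
birth function. At $\beta = 1/2$, $\alpha = -1$ the mean evaluates
*exactly* to $2mf/(m+f)$, the harmonic form used in all worked models,
so the package's `scale` multiplier defaults to 1 and
`mating_spec("generalized", beta = 0.5, alpha = -1)` coincides with
`mating_spec("harmonic")` to machine precision (asserted in the test
suite); the multiplier is exposed only as a knob for nonstandard
calibrations. The geometric ($\alpha \to 0$) and minimum
($\alpha \to -\infty$) members are provided for comparison; at
$\alpha = -a$ the generalized mean sits within a relative factor
$2^{1/a}$ of $\min(m, f)$, which is the bound the limit test uses
(about 1.4% at $a = 50$, 0.7% at $a = 100$).

Per-capita rates are $U_m = M/m$ and $U_f = M/f$. On the boundary, where
the own-sex density is zero, the package substitutes the finite
algebraic limit (for the harmonic family $U_m \to 2$ as $m \to 0$ with
$f > 0$); the limit always multiplies a zero density, so no spurious
flux is created, but the right-hand side of the simplex dynamics stays
defined. Where the limit genuinely diverges (geometric family) the rate
is set to 0, again without affecting any flux. When both sexes are
absent all mating quantities are 0.

### Polygyny

For maximum harem size $h$ the stage space carries $h$ union stages;
$u_i$ is one male with $i$ females. Three conventions, each adopted from
the canonical formulation and fixed throughout:

* **Unions form at full size.** New unions enter $u_h$ only; the mating
  function is evaluated on prospective harems, i.e. at $(m_2, f_2/h)$,
  giving $M = 2 m_2 f_2 / (h m_2 + f_2)$ for the harmonic family. A
  consequence worth knowing: the total mating rate is maximized when
  single males are a fraction $1/(1+\sqrt h)$ of single adults, so
  larger harems need a more female-biased singles pool.
* **Unions shrink, never grow.** Female death or divorce moves $u_i$ to
  $u_{i-1}$; from $u_1$ both members return to the single stages. The
  male leader's death dissolves the union, returning $i$ females to
  `f2`. Single males re-enter `m2` only through full dissolution.
* **One female death event per union per unit time.** The transition
  matrix charges female mortality inside $u_i$ at rate $\mu_{f2}$, not
  $i\,\mu_{f2}$ — a transcription of the canonical rate matrices rather
  than a per-individual reading of the verbal rules. This asymmetry
  (male deaths are charged per harem at $i\,\mu_{m2}$ flowing females
  back, female deaths once per union) is what makes the equilibrium
  adult sex ratio of the polygynous model slightly female-biased even
  with fully symmetric vital rates; the per-individual variant, exposed
  as `transition_matrix(..., per_individual_female_mortality = TRUE)`,
  restores exact symmetry ($s_2 = 1/2$) and is provided as a documented
  extension, default off.

Monogamy is represented as the $h = 1$ special case of the polygynous
builder — one code path; a dedicated test checks cell-for-cell agreement
with the printed five-stage matrices.

### Conservation accounting

Each stage carries content weights: individuals per unit
(`multiplicity`), adult males, and adult females. Contracting a process
matrix with the multiplicity weights isolates the individual flux the
process creates or destroys, giving exact invariants the suite enforces
at $10^{-12}$ on randomized models: union formation and divorce conserve
individuals, transitions lose exactly the death flux, births add
$k \sum_i i\,u_i$. For $h > 1$ the union-formation identity holds only
after contraction with the composition (the $m_2$ and $f_2$ columns
carry compensating $\pm(h-1)/2$ terms that cancel through
$U_m m_2 = U_f f_2 = M$), so the tests assert the contracted identity
$\mathbf{mult}^\top \mathbf U \mathbf n = 0$ rather than a column-wise
zero.

The same weights define the population outputs: the secondary sex ratio
$s_2$ counts *all* adult individuals — harem leaders and members
included — and the proportion mated counts adult individuals inside
unions. Counting union members is deliberate: it is the accounting under
which the symmetric monogamy model yields exactly $s_2 = 1/2$ and the
polygynous model its characteristic slight female bias; the obvious
alternatives (one male + one female per union regardless of harem size,
or singles only) give adult male fractions above 0.55 and are not
sex-ratio summaries of the population at all.

## Numerical choices

**Integrator.** The simplex dynamics are smooth and non-stiff;
`equilibrate()` uses `deSolve`'s adaptive Runge–Kutta 4/5 pair
(`ode45`), with `rtol = 1e-10`, `atol = 1e-12`. The residual
$\|d\mathbf p/dt\|_\infty$ attainable at the integrator's terminal point
is bounded below by the integration error, so `rtol` must sit well
below the convergence tolerance; with the defaults the dual criterion
at `tol = 1e-10` is reachable in a few tens of time units for all the
parameterizations the package ships.

**Convergence.** Declared when both the max-norm change of $\mathbf p$
across a 10-time-unit checkpoint window *and*
$\|d\mathbf p/dt\|_\infty$ fall below `tol` ($10^{-10}$ by default);
requiring both guards against slow transients masquerading as
equilibria. Failure to converge by `t_max` ($10^4$) returns a flagged
result with the residual, never an error, so sweeps report rather than
drop pathological combinations. Negative round-off frequencies are
clipped and the vector renormalized at checkpoints only; the right-hand
side the integrator sees is never altered, preserving its error model.

**Initial composition.** Uniform over stages by default (no canonical
choice exists); the equilibrium is independent of the interior starting
point, which the suite verifies by comparing two distant starts at
$10^{-6}$, and the acceptance script exercises with seeded random
starts.

**Growth rate.** $\lambda$ is the eigenvalue of
$\mathbf A[\hat{\mathbf p}]$ with the *largest real part* — the
continuous-time convention ($e^{\lambda t}$ growth; $\lambda$ may be
negative), not largest modulus. For matrices with nonnegative
off-diagonals this eigenvalue is real with a nonnegative eigenvector;
`growth_rate_and_structure()` verifies realness and sign-coherence and
errors with diagnostics if dominance is ambiguous (e.g. the all-zero
model). The eigenvector route is cross-checked against an independent
oracle: the late-time slope of $\log\|\mathbf n(t)\|_1$ from direct
density integration, required to agree within $10^{-4}$ on six
parameter sets spanning monogamy, polygyny, and biased harvest.

**Harvest.** `apply_harvest()` folds $E$, $s_h$ into the adult
mortalities ($\mu_{m2} + E s_h$, $\mu_{f2} + E(1-s_h)$; juveniles are
never harvested) and zeroes $E$, so harvest cannot be applied twice;
`equilibrate()` and the sweep do this automatically. Sweep deltas are
taken against the matched baseline: the same parameter combination with
$E = 0$ (cached, since it is independent of $s_h$).

## What the test problems do and do not show

The shipped parameterizations use symmetric vital rates (juvenile
mortality 0.5, adult mortality 0.1, maturation 0.5 for both sexes,
$k = 20$ offspring per female per unit time, even primary sex ratio),
divorce rates 0–2 and harem sizes 1–10 — deliberately idealized
conditions under which every sex difference in the output is
attributable to the mating system or to harvest, not to the inputs.
The suite's problem sizes — equilibrations of 5–14-stage systems, grids
of a few dozen combinations, horizons of at most a few hundred time
units — keep the whole suite under half a minute.

Real populations break these idealizations in ways the model does not
represent: vital rates vary in time and space, mating seasons are
discrete, harem sizes are distributions rather than a hard maximum,
divorce and mortality are not independent, and parameter values carry
sampling error. Passing tests show the machinery is a faithful and
internally consistent implementation of the model; they do not validate
the model's behavioral assumptions (females-only divorce, full-size
union formation, one-female-death-per-union) for any particular
species.

A known quantitative nuance, surfaced by the acceptance suite: over the
$h \in \{2..10\} \times d \in \{0,...,2\}$ grid the unharvested
polygynous adult sex ratio spans roughly 0.490–0.497 (most biased at
large $h$, small $d$), so a single representative value for this bias
is accurate only to a few thousandths.

## Limitations

* One interbreeding class per sex; no stage-specific mating preferences
  or typed unions.
* Polygyny only; no polyandry, no couple-duration structure.
* Constant environment: no seasonality, stochasticity, or space.
* Global convergence of the frequency dynamics is assumed (it holds for
  every parameterization exercised here); limit cycles, if a parameter
  set produced them, would surface as `converged = FALSE`, not be
  analyzed.
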