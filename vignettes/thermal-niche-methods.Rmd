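---
title: "Trait-based thermal niche modelling: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based thermal niche modelling: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermalniche)
library(dplyr)
```

## The modelling framework

`thermalniche` predicts where an ectotherm can live from laboratory trait
measurements alone. The chain of inference is:

1. **Thermal reaction norms.** Each life-history trait gets a mechanistic
   temperature response: birth rate $b(T)$ is Gaussian (regulatory processes
   push reproduction toward an intermediate optimum), juvenile and adult
   mortality $d_J(T), d_A(T)$ follow the Boltzmann–Arrhenius law of reaction
   kinetics (monotone increase with warming), and the maturation rate
   $m_J(T)$ follows the Sharpe–Schoolfield thermodynamic rate-process model —
   an Arrhenius core damped by low- and high-temperature enzyme-inactivation
   terms, producing the left-skewed curve typical of development data.
   Temperatures are Kelvin everywhere inside the package.

2. **Stage structure with temperature-dependent delays.** The population is
   split into non-reproductive juveniles $J$ and reproductive adults $A$.
   Juveniles born at time $t-\tau(t)$ mature at $t$, having survived the
   stage with probability $S_J(t)$. When temperature varies, $\tau$ and
   $S_J$ obey their own delay differential equations derived from the
   maturation-index identity $\int_{t-\tau(t)}^{t} m_J[T(x)]\,dx = 1$ (each
   individual accumulates one unit of development before maturing).

3. **Intrinsic growth rate in closed form.** At constant temperature the
   long-term growth rate of the density-independent model is
   $$r(T) = -d_A(T) + \frac{1}{\tau(T)}
     W\!\big(b(T)\,\tau(T)\,e^{\tau(T)(d_A(T)-d_J(T))}\big),$$
   with $W$ the principal Lambert branch and $\tau(T)=1/m_J(T)$. The
   *fundamental thermal niche* is the interval $(T_{\min}, T_{\max})$ on
   which $r(T) > 0$; its interior maximum $T_{opt,r}$ is where the species
   increases fastest when rare.

4. **Density dependence and the climate envelope.** Self-limitation enters
   as $B = b\,e^{-q_b A}$ (crowding depresses fecundity) or
   $D_X = d_X (1 + q_{dX} X)$ (crowding raises mortality), with the
   per-capita competition coefficient $q(T)$ itself temperature-dependent:
   monotonically increasing (Arrhenius — activity, hence resource demand,
   rises with temperature) or unimodal (Gaussian — demand peaks at the
   reproductive optimum). In a constant environment the adult equilibrium is
   closed-form: with $R_0(T) = b\,S_J/d_A$,
   $A^* = \ln R_0 / q_b$ under fecundity regulation and
   $A^* = (R_0 - 1)/q_d$ under adult-mortality regulation.

5. **Stability and recovery.** Linearizing the adult equation about $A^*$
   gives the scalar delayed characteristic equation
   $\lambda = -a + c\,e^{-\lambda\tau}$. Its dominant root determines
   stability and the recovery time
   $t_{rec} = -\mathrm{Re}\,\lambda / |\lambda|^2$.

The two shipped parameter sets describe a naturalized Mediterranean-adapted
species (harlequin bug) and a recent subtropical invader (bagrada bug) of
the southern-California coastal sage scrub; a third, synthetic
"generic" warm-adapted parameter set is used for qualitative analyses.

## Parameters that matter, and defaults

| Parameter | Units | Default | Why |
|---|---|---|---|
| `t_ref` | K | 297 | reference temperature inside the 100%-enzyme-activity range (20–30 °C) at which reference trait values are measured |
| competition baseline `strength` | per individual | 0.1 | the standard self-limitation strength used in the two-species comparison; abundances scale as $1/q$, optima do not move |
| `search_range` | K | (274, 323) | spans all plausible insect niches while avoiding the cold-side blow-up of $\tau(T)$ |
| DDE `step` | d | 0.05 | output/integration step; max per-day rate times step stays well below 0.1 |
| `horizon` | d | 1825 | five years — long enough for a stable stage distribution across the whole niche |
| generator `noise_sd_frac` | – | 0.05 | 5% multiplicative measurement noise, typical of replicate trait assays |
| generator `n_per_temp` | – | 10–20 | replicate counts comparable to laboratory rearing experiments |

### The Celsius convention

All computation is in Kelvin; Celsius appears only at the I/O boundary.
`kelvin_to_celsius()` subtracts **273** by default rather than 273.15: the
shipped parameter sets were estimated under the convention that freezing is
273 K (the low half-activity temperature of maturation is pinned at
"freezing = 273 K"), and reported Celsius optima are only consistent with
the Kelvin-domain fits under that same offset. The difference is 0.15 °C,
irrelevant to any biology but visible at the 0.1 °C precision to which
optima are reported. The offset is an explicit argument for users who prefer
the exact convention.

## What the synthetic-data generator does and does not emulate

`generate_trait_data()` draws replicate trait values at a handful of
constant temperatures — by default the eight experimental treatments
(15–35 °C) of the harlequin rearing study — as
$\text{truth}(T)\,(1 + \mathcal N(0, \sigma))$, truncated at zero, then
aggregates to the mean/SE/n form in which such experiments are analysed.
That reproduces the *estimation geometry* of real trait assays (few
temperatures, moderate replication, roughly proportional noise) and lets us
test parameter recovery against a known truth.

It does **not** emulate: count-type noise in fecundity (overdispersed,
integer), censoring of development times at lethal temperatures, individual
heterogeneity or shared-chamber correlation, or unequal replicate counts
across temperatures. Passing recovery tests therefore demonstrate that the
estimator is correct and well-calibrated under clean Gaussian sampling — not
that every real dataset will yield equally tidy estimates.

## Fitting: optimizer, pins, identifiability

Fits minimize the residual sum of squares between the family curve and the
per-temperature trait means; when the table carries (all-positive) standard
errors of those means, each temperature is weighted by the inverse squared
SE — means of unequal precision should not count equally, and under the
roughly proportional noise of trait assays unweighted SEs miscalibrate
badly for peak-type parameters (`weights = "none"` restores plain least
squares). Optimization is Levenberg–Marquardt, with box bounds encoding
biological realism: positive rates and breadths, half-activity temperatures
above freezing and ordered). The skewed maturation surface has genuine local
minima in the (high half-activity temperature × Arrhenius constant) plane,
so every fit multi-starts from a coarse grid over the location parameter;
ties are broken by lowest SSR, then lowest parameter norm.

Reference-temperature trait values ($m_{T_R}$, $d_{X T_R}$) are observed at
$T_R$ rather than estimated, so they are passed as pins (`fixed=`) and
reported without standard errors. When the data do not reach far enough
above the optimum to constrain the high-temperature decline of maturation —
as for the bagrada — the reduced `schoolfield_high` family is used with the
decline parameters pinned at assigned values; pins always appear in the fit
report. Standard errors are asymptotic
($\hat\sigma^2 (J^\top J)^{-1}$), t statistics use the residual degrees of
freedom, and p-values are two-sided — the conventions of `nls`-style output.
A fit whose SE exceeds the estimate triggers a "weakly identified" warning
(one-sided temperature coverage of a Gaussian optimum is the canonical
case); a rank-deficient normal matrix is an error naming the unidentifiable
parameter, never a silently confident answer.

## Numerical choices

**Lambert W.** Both real branches are computed in-package by Halley
iteration. Near the niche edges $\tau(T)$ reaches $10^4$–$10^5$ days and the
W argument $b\tau e^{\tau(d_A-d_J)}$ overflows double precision, so the
principal branch also accepts the *logarithm* of its argument and solves
$w + \log w = \log x$ instead; $r(T)$ is therefore evaluable arbitrarily
deep into the tails, which the bracketed root-finding for $T_{\min}/T_{\max}$
relies on. Residual identities ($|w e^w - x| < 10^{-10} x$) are asserted in
the tests.

**Characteristic roots.** $\lambda = -a + c\,e^{-\lambda\tau}$ is solved via
$u e^u = c\tau e^{a\tau}$ on Lambert branches, again in log form
($u + \mathrm{Log}\,u = \log|c\tau| + a\tau + i\pi[c<0] + 2\pi i k$), so
large $a\tau$ never overflows. The maximal-real-part root across branches
$k = 0,\dots,6$ (conjugates implied) is the dominant eigenvalue; an
argument-principle winding count over a rectangle of the complex plane
independently verifies root counts in the tests, and every returned root
must satisfy its equation to $10^{-10}(|a|+|c|)$.

**DDE integration.** The default integrator is `deSolve::dede` (adaptive
LSODA with dense interpolated history for the state-dependent lag
$t - \tau(t)$; tolerances `rtol = 1e-8`, `atol = 1e-10`). A fixed-step
classical RK4 by the method of steps, with cubic-Hermite history
interpolation, is available as `method = "rk4"` for step-convergence
studies; it requires (and enforces) that the delay spans at least two steps,
which holds by orders of magnitude for developmental delays of weeks at
steps of a fraction of a day.

**Initial conditions.** Abundances start at $A(0)=1$, $J(0)=0$ with constant
pre-history; the five-year horizon erases their influence. The initial delay
solves the maturation-index identity
$\int_{-\tau_0}^{0} m_J[T(x)]\,dx = 1$ (reducing to $1/m_J(T(0))$ under
constant forcing) and initial survivorship is the matching integrated
survival over $(-\tau_0, 0)$. This consistent initialization makes the
maturation index *exactly* conserved by the continuous dynamics, so its
numerical drift is a direct audit of the delay integration — the package
checks it stays within $10^{-3}$ of 1 under seasonal forcing and shrinks at
least linearly under step halving.

**Root/optimum location.** $T_{opt,r}$ by bounded golden-section/parabolic
maximization (tolerance $10^{-4}$ K); $T_{\min}, T_{\max}$ by bracketed
root-finding seeded from sign changes of the sampled $r$ curve (0.05 K
grid, tolerance $10^{-6}$), taking the bracket nearest the optimum (with a
warning) if the flat tails of a reduced maturation form ever produce
multiple crossings. Overlap integrals use adaptive quadrature (absolute
tolerance $10^{-8}$), and the niche intersection is located to
$|r_a - r_b| \le 10^{-6}$.

**Overlap fractions.** The shared niche is quantified as the area under the
*lower envelope* of the two $r(T)$ curves over the overlap interval —
equivalently the sum of each species' one-sided integral split at the
intersection temperature — and each species' overlap fraction divides that
shared area by the integral of its own $r(T)$ over its full niche. A
width-based ratio (overlap width over niche width) is *not* used: growth
rates near the niche edges are vanishingly small, so interval widths
overstate how much usable niche is shared.

## Design choices made where the design was open

- **Density-dependent mortality form.** The mortality response to density is
  implemented as $d_X (1 + q\,X)$ — mortality rising linearly with
  crowding. A divisive reading ($d_X/(1+qX)$, mortality *relieved* by
  crowding) admits no positive equilibrium under these trait values and is
  biologically backwards for resource competition.
- **Standard competition configurations.** For the two-species comparison,
  fecundity regulation pairs with the unimodal response centred on each
  species' own reproductive optimum (breadth equal to the birth breadth),
  and mortality regulation pairs with the monotonic response sharing the
  adult-mortality Arrhenius constant, both at baseline 0.1 — competition
  intensity tracking the trait it acts upon. Both shapes remain
  user-selectable for either trait via `competition_spec()`.
- **Scalar linearization.** Stability uses the adult equation only: at
  constant temperature $S_J$ and $\tau$ are constants and the juvenile class
  feeds back on adults exclusively through the delayed adult term, so the
  adult dynamics close on themselves. The reduction is guarded by a
  simulation oracle — fitted decay rates of perturbed trajectories must
  match $-\mathrm{Re}\,\lambda$ within 5%, and ring-down periods
  $2\pi/|\mathrm{Im}\,\lambda|$ likewise.
- **Equilibria on fecundity/adult-mortality regulation only.** Juvenile-stage
  density dependence is simulated but has no closed-form equilibrium here
  (the Hemipteran systems motivating the framework concentrate density
  effects in the adult stage); requesting one raises a clear
  not-implemented error.

## Problem sizes used in the shipped checks

The test-suite simulations use 3–9-year horizons at output steps of
0.25–0.5 d for oracle comparisons, 0.1–0.4 d for convergence studies; the
density-independent envelope is profiled at 0.5 K over each species' niche
with the 5-year protocol; Monte-Carlo recovery uses 200 replicate syntheses
at 5% noise with 20 replicates per temperature. These sizes make every
cross-check sharp (agreements at $10^{-3}$ or better for equilibria,
1% for growth slopes) while keeping the whole suite comfortably fast.

## Known limitations

- Recovery-time *magnitudes* depend on the normalization of the dominant
  eigenvalue and are best treated as relative; the temperature at which
  recovery is fastest is scale-invariant (rescaling all rates by a common
  factor moves $\lambda$ linearly and recovery reciprocally, leaving the
  argmin fixed) and is the quantity to compare across studies. For
  fecundity-regulated populations the recovery time is additionally
  *independent of the competition coefficient* ($q_b A^* = \ln R_0$ exactly),
  a structural fact worth knowing before attributing recovery differences to
  competition strength.
- No interspecific competition dynamics: species are compared through their
  separate single-species models and the geometry of their $r(T)$ curves.
- One juvenile class; systems with stage-specific density dependence need
  the juvenile class split, which this package does not do.
- Temperature is the only abiotic driver; humidity/salinity analogues would
  need their own response families.
- Forcing is deterministic (constant or sinusoidal); no stochastic weather.

## A compact worked example

```{r example}
bag <- tn_species("bagrada")
har <- tn_species("harlequin")

niche_metrics(har)
niche_overlap(bag, har)
```

```{r simulate}
m <- model_spec(har, default_competition(har, "adult_mortality"),
                temperature_forcing("constant", celsius_to_kelvin(23.7)))
equilibrium(m)
dominant_eigenvalue(m)
```
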