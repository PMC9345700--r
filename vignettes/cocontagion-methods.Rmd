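---
title: "Methods: the violence–racism co-contagion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the violence–racism co-contagion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocontagion)
```

## The model and its assumptions

`cocontagion` treats violence and racism as two chronic, socially
transmitted conditions in a homogeneously mixing community. Eight
mutually exclusive compartments partition the population: susceptible
$S$, violence-infected $V$, negotiated $U$, racism-infected $R$,
coinfected $I_{vr}$, and recuperated classes $R_1, R_2, R_3$ (from
violence, racism, and coinfection respectively), with
$N = S+V+U+R+I_{vr}+R_1+R_2+R_3$. The forces of infection are

$$\lambda_v = \beta_1 (V + \theta_2 I_{vr}), \qquad
  \lambda_r = \beta_2 (R + \theta_1 I_{vr}),$$

i.e. coinfected individuals transmit each behaviour like singly
infected ones, rescaled by the modification factors $\theta_1,
\theta_2$. The factored form matters: it is what makes the
next-generation matrix carry the entries
$\beta_1\theta_2\Lambda/\mu$ and $\beta_2\theta_1\Lambda/\mu$ that the
closed-form reproduction numbers rest on, and the package adopts it
throughout. The full system is given in `rhs_full()` (see the README
for the equations); `rhs_violence()` and `rhs_racism()` are the exact
restrictions obtained by emptying the other behaviour's compartments,
and the test suite asserts this embedding identity directly.

Key structural assumptions: recruitment at constant rate $\Lambda$ and
exit at per-capita rate $\mu$ (so $N' = \Lambda - \mu N$ exactly);
mass-action incidence; no simultaneous double transmission (coinfected
individuals pass on one behaviour per contact); recuperated individuals
return to full susceptibility. Time is measured in years, the natural
unit for the per-year rates and multi-year horizons of the scenario
experiments.

## Parameters

Sixteen nonnegative constants (`model_parameters()`): $\Lambda$
(persons/yr), $\mu$ (1/yr, strictly positive), transmission rates
$\beta_1, \beta_2$ (1/(person·yr)), modification factors $\theta_1,
\theta_2, \beta, \kappa$ (dimensionless; `beta_mod` and `kappa` in
code), and the transfer rates $\delta, \varepsilon, \alpha, \sigma,
\rho, \omega, \phi, \theta$ (all 1/yr). The reference preset fixes
$\mu = 0.01$, $\alpha = 0.51$, $\varepsilon = 0.60$, $\sigma = 0.50$,
$\delta = 0.40$, $\kappa = 1.3$, $\rho = 0.61$, $\theta = 0.72$,
$\beta = 1.2$, $\omega = 0.60$, $\phi = 0.50$.

Two documented inconsistencies in the reference material shape the
presets:

* **Recruitment rate.** The tabulated $\Lambda = 50$ is inconsistent
  with the quoted thresholds $\mathcal{R}_0^v = 3.7$ (at
  $\beta_1 = 0.003$) and $\mathcal{R}_0^r = 6.9$ (at
  $\beta_2 = 0.007$), which require $\Lambda = 5$ (then
  $3.6585 \approx 3.7$ and $6.8627 \approx 6.9$; with $\Lambda = 50$
  one gets 36.6 and 68.6). Both readings ship: `table2_printed` and
  `table2_reconciled`. The reconciled preset is the default base for
  the scenario presets because it reproduces the headline thresholds.
* **Control rate $\omega$.** The reference table lists $\omega$ twice
  (0.60 and 0.42); the second row's intended parameter is unknowable,
  so the presets use 0.60 and the duplicate is simply not assigned to
  anything.

$\theta_1, \theta_2$ have no tabulated values and default to 1
(coinfected transmit like singly infected) — a neutral choice exposed
in every config.

## Reproduction numbers

Linearizing the infected subsystem $(V, R, I_{vr})$ at the
contagion-free equilibrium $S_0 = \Lambda/\mu$ gives the
next-generation pair ($F$ new infections, $V$ transitions; see
`build_ngm()`), with

$$\mathcal{R}_0^v = \frac{\beta_1 \Lambda}{\mu(\delta+\mu)}, \qquad
  \mathcal{R}_0^r = \frac{\beta_2 \Lambda}{\mu(\sigma+\mu)}, \qquad
  \mathcal{R}_0^{vr} = \max(\mathcal{R}_0^v, \mathcal{R}_0^r).$$

The third row of $F$ is zero — new coinfections arise only through the
nonlinear incidence, absent at the linearization point — so
$FV^{-1}$ has exactly the two submodel thresholds as nonzero
eigenvalues. The package computes the spectral radius with a general
eigensolver and cross-checks it against the closed forms to $10^{-9}$
over a thousand random draws; in the scalar (submodel) case the two
routes share the same operation order so they agree bitwise. One
transition-matrix subtlety: the raw transition list for the $R$ class
contains a $\beta\lambda_v$ term, which vanishes at the linearization
point, so $v_{22} = \sigma + \mu$.

## Equilibria and stability

Both submodels have closed-form endemic states, parameterized by the
equilibrium force of infection, e.g.

$$\lambda_v^* = \frac{(\alpha+\mu)(\varepsilon+\mu)\,\mu(\delta+\mu)
  (\mathcal{R}_0^v - 1)}
  {(\alpha+\mu)(\varepsilon+\mu)(\delta+\mu) -
   \alpha\varepsilon\delta},$$

positive exactly when $\mathcal{R}_0^v > 1$ (the denominator is
positive for $\mu > 0$); `endemic_violence()` and `endemic_racism()`
back-substitute the compartments and refuse to run below threshold.
Every equilibrium is returned as a report carrying the RHS residual
(closed forms meet $\|f\|_\infty < 10^{-10}\Lambda$), the Jacobian
eigenvalues and a verdict.

The full model's endemic state has no closed form. `endemic_full()`
polishes the endpoint of a long integration with a damped Newton
iteration (step solved by `solve()` on the finite-difference Jacobian,
halving the step while the residual grows, cap 200 iterations,
convergence at step $< 10^{-10}$ or residual $< 10^{-8}\Lambda$; roots
with components below $-10^{-8}\Lambda$ are rejected). The Jacobian is
differentiated numerically — central differences with relative step
$10^{-6}$, which are *exact* (up to rounding) here because the vector
field is quadratic in the state. This numeric route replaces the
printed closed-form Jacobian of the source material, whose $D_2$ and
$\lambda_5$ entries mix up $(\delta+\mu)$ and $(\sigma+\mu)$; the test
suite asserts the $(\sigma+\mu)$ version, which is the one consistent
with the racism submodel's characteristic polynomial.

Stability verdicts use a $\pm 10^{-9}$ band on eigenvalue real parts:
anything inside it is reported `"marginal"`, never silently rounded to
stable or unstable.

A fact worth knowing about the dynamics: under the persistence preset
(`fig5_persistence`, $\beta_1 = 0.001$, $\beta_2 = 0.004$) the system
converges to a *boundary* root with racism endemic and
$V = U = I_{vr} = R_1 = 0$. The coinfected class is transient there —
its exit rate $\phi + \omega + \mu \approx 1.11$/yr outpaces its
nonlinear inflow near equilibrium — so "persistence" means persistence
of the dominant behaviour, not of coinfection. `endemic_full()` with
default arguments finds exactly this attractor because its default
guess is the simulated long-time state.

## Sensitivity analysis

The normalized forward sensitivity index (elasticity)
$SI(p) = \frac{\partial \mathcal{R}_0}{\partial p}\frac{p}{\mathcal{R}_0}$
has closed forms for both thresholds: $+1$ for the transmission rate
and $\Lambda$, $-\delta/(\delta+\mu)$ (resp. $-\sigma/(\sigma+\mu)$)
for the removal rate, and $-1 - \mu/(\delta+\mu)$ for $\mu$; all other
parameters are exactly 0. An independent finite-difference route
(central difference on a multiplicative perturbation, default
$h = 10^{-6}$) agrees to $10^{-6}$ relative across random draws, and
the four nonzero indices sum identically to zero — a small algebraic
identity the tests assert.

At the reference values the analytic removal-rate indices are
$-0.9756$ ($\delta$) and $-0.9804$ ($\sigma$), and the $\mu$ indices
$-1.0244$ and $-1.0196$. The reference material prints $-0.81$,
$-0.86$, $-0.31$, $-0.34$ for these — values not reproducible from its
own definition at any of its printed parameter sets. The package
follows the definition; only the $+1$ entries are treated as reference
results.

Because $\mathcal{R}_0^{vr} = \max(\cdot,\cdot)$ is not differentiable
at a tie, the full-model report delegates to whichever submodel
threshold is strictly larger and raises an error on an exact tie.

## Simulation choices

Integration uses the Dormand–Prince 4(5) pair (`deSolve`'s `ode45`)
with `rtol = 1e-8`, `atol = 1e-10` — the system is non-stiff and cheap,
so tight tolerances cost little — reporting on an even grid of 201
times by default. Two analytic oracles guard accuracy: $N(t)$ must
track its exact scalar solution
$\Lambda/\mu + (N(0)-\Lambda/\mu)e^{-\mu t}$ to $10^{-6}$ relative,
and halving the tolerances must move reported states by less than
$10^{-4}$ relative.

**Positivity handling.** Adaptive explicit solvers legitimately
undershoot exponentially decaying compartments by amounts of the order
of the requested accuracy: with populations of a few hundred,
undershoots of $\sim 10^{-8}$ persons occur at these tolerances. The
default budget is therefore $\max(10^{-9},\; \mathrm{rtol}\cdot N(0))$:
reported values inside $(-\mathrm{budget}, 0)$ are clipped to zero and
counted (`n_clipped` attribute), anything below the budget aborts with
the offending compartment, time and tolerances — solver
misconfiguration should surface, not be clipped away.

**Initial states.** The reference material never prints its simulation
initial conditions. The package default
(`default_initial_state()`) seeds one person in each contagious class
($V$, $R$, $I_{vr}$) of an otherwise susceptible population of
$\Lambda/\mu$. For the control-rate experiments
(`control_effect()` over $\omega, \phi \in \{0.6, 0.7, 0.8\}$) the
examples and tests instead start from an established outbreak
($S{=}400, V{=}50, R{=}40, I_{vr}{=}10$ out of 500): from the minimal
seed the coinfected class only decays, so every control value would
share the identical "peak" $I_{vr}(0)$, whereas a control experiment
is meaningful when the epidemic is under way and the peak is interior.
With that start, both the peak and the terminal coinfection level
decrease strictly in either control rate.

**Horizons.** Eradication checks run 200 years (sub-threshold decay
rates here are $\gtrsim 0.04$/yr, so transients are long gone);
persistence runs 500 years to reach the plateau governed by the slow
$\mu = 0.01$/yr demographic mode; property tests over random draws use
400 years with draw ranges chosen so the slowest relevant rate stays
above $\sim 0.04$/yr. The quoted "$\mathcal{R}_0^{vr} = 0.32$" for the
eradication figure of the reference material is not reproducible from
any of its printed parameter sets, so eradication is asserted as the
qualitative outcome (infected classes below $10^{-3}$ persons at the
horizon end), not as that number.

## What the generator emulates — and what it does not

Scenario presets and the random-draw helpers generate exactly the
study conditions above: fixed rates, deterministic homogeneous mixing,
constant recruitment. Passing tests therefore certify the mathematics
of this model, not its fit to any real community: there is no
demographic or network heterogeneity, no age or spatial structure, no
stochasticity (all out of scope here), and the behavioural rates
themselves are assumptions rather than estimates from data. Conclusions
about real interventions would need the model calibrated to
observations, which is beyond what this package claims.

## Known limitations

* Global stability is checked numerically (random initial conditions
  converging to the contagion-free state below threshold), not by
  Lyapunov certificates.
* The full-model endemic state is only available numerically; its
  basin and possible coexistence of attractors are not mapped.
* `max`-type thresholds make full-model sensitivity undefined at
  exact submodel ties (reported as an error, by design).
* The CLI is a thin convenience wrapper; programmatic use through the
  package functions is the supported interface.
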