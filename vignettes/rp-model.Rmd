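---
title: "The replicase-parasite model at two observation scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The replicase-parasite model at two observation scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpsim)
```

## The model

An RNA-world population is reduced to two molecular species plus an
abiotic resource.  *Replicases* (density $r$) are RNA molecules with
polymerase activity: they copy any template they encounter, including
themselves.  *Parasites* (density $p$) carry no catalytic activity and
only get copied.  Replication is a third-order mass-action reaction —
enzyme, template, and one unit of *resource* ($n$) must meet — whose rate
constant is the template's affinity towards replicases: $a_R$ for
replicase templates, $a_P$ for parasite templates.  Copying a replicase
fails with *miscopy probability* $m$ and then yields a parasite.  Both
RNA species decay at first-order rates $d_R$, $d_P$; resources are
produced at a constant rate $n_0$ and everything diffuses (constants $D$
for RNA, $D_n$ for resources).  The macroscopic dynamics are

$$
\begin{aligned}
\partial_t n &= n_0 - n r (a_R r + a_P p) + D_n \nabla^2 n,\\
\partial_t r &= (1-m)\, a_R n r^2 - d_R r + D \nabla^2 r,\\
\partial_t p &= m\, a_R n r^2 + a_P n r p - d_P p + D \nabla^2 p.
\end{aligned}
$$

The scientific question is whether such a population can persist at all:
parasites are replicated for free, and natural selection among templates
favors ever-better parasites.

## Closed-form well-mixed analysis (`analytic` functions)

Setting all gradients and time derivatives to zero gives a unique
positive steady state whenever $0 < m < 1$ and the **persistence
inequality**

$$ 1 - m \;>\; \frac{a_P d_R}{a_R d_P} $$

holds (`persistence_margin()` returns the signed slack).  The state is

$$ A = \frac{m a_R d_R}{d_P(1-m)a_R - a_P d_R}, \qquad
   n^* = \frac{d_R^2 (a_R + a_P A)}{n_0 [(1-m)a_R]^2}, \qquad
   r^* = \frac{d_R}{(1-m) a_R n^*}, \qquad p^* = A r^*, $$

implemented in `steady_state()`, which the tests verify by plugging the
result back into the balance equations.  At $m = 0$ the equilibrium
degenerates (coexistence in any proportion iff $a_R d_P = a_P d_R$), and
the function returns a degenerate-case object rather than a point.

Linearizing the replicase equation about the equilibrium leaves the
strictly positive rate $(1-m) a_R n^* r^*$ (`linear_growth_rate()`):
replicase perturbations are initially self-amplifying, so linearization
cannot settle stability.  Substituting $y = 1/r$ with the parasite
density frozen turns the homogeneous system into a damped-pendulum
equation $y'' = P(y) + Q(y)\,y'$ with

$$ P(y) = d_R a_P p - n_0(1-m)a_R + \frac{d_R a_R}{y}, \qquad
   Q(y) = d_R - \frac{a_P p}{y} - \frac{a_R}{y^2}. $$

`pendulum_coefficients()` returns the equilibrium root $y_E$ and the
critical point $y_C$ (the largest zero of $Q$); below $y_C$ the friction
is negative and trajectories spiral into $y_E$, beyond it the friction
term feeds energy in and $y \to \infty$, i.e. the replicases collapse.
`integrate_pendulum()` and `integrate_well_mixed(clamp_p = TRUE)`
realize the two routes and agree to discretization error; the frozen-$p$
approximation is exposed as a flag rather than hidden, because no
quantitative validity bound is available — it simply fails when the
parasite density moves on the same time scale as $y$.

Numerical choices: all analytic-module integrations use fixed-step
classical Runge-Kutta (RK4) with densities projected onto $\ge 0$ after
each step; the default step is the lattice step 0.1, but several regimes
in the tests use finer steps because the resource relaxation rate
$n_0/n^*$ can be large.  `integrate_pendulum()` flags divergence when
$y$ exceeds $10^6\, y_E$, a scale separation that cannot be crossed by a
bounded oscillation.  The damped-oscillation (underdamped) regime
requires weak friction at the equilibrium, $Q(y_E)^2 < 4\,|P'(y_E)|$;
with $a_R = n_0 = 1$, $p$ small, that needs a high turnover
$d_R \gtrsim 0.63$, which is why the oscillation demonstrations in the
tests use $d_R = d_P = 0.8$ rather than the lattice default 0.01.

## The lattice simulator (`pde_*`, `run_pde()`)

The reaction-diffusion system is integrated by forward Euler on a
periodic 2D lattice (spacing 1, absorbed into $D$), with a fixed
per-cell update order: offspring demand is computed first and, if it exceeds the locally available
resource, both offspring kinds are rescaled so consumption equals $n$
(resource limitation); then growth, decay, and diffusion are applied;
negatives are clamped to zero.  Diffusion is the discrete exchange
`D*dt*(avg - self)` where `avg` is the neighbor average.

**Neighborhood.**  "Adjacent neighbors" is read as the 8-cell Moore
ring, not the 4-cell von-Neumann cross, and this choice is forced by
stability rather than taste: at the default parameters
$D_n \Delta t = 1$, so the resource update degenerates to
`n <- avg(n)`.  Under the 4-neighbor average the checkerboard mode has
eigenvalue $-1$: the resource field decouples into two sub-lattices that
swap every step, and the $\ge 0$ clamp plus the consumption cap rectify
that neutral oscillation into unbounded spurious growth (total RNA mass
exceeding cumulative resource production within a few hundred steps).
The 8-neighbor average has spectrum $(-\tfrac12, 1]$ and no such mode.
Both variants are implemented (`neighborhood` in `pde_run_config()`, and
in `neighbor_average()`), and the compiled kernel is tested cell-by-cell
against a literal R transcription for both.

**Evolving parasite affinity.**  The local mean parasite affinity $a$ is
carried as a fourth field.  Because affinity is transported by parasites,
its diffusion is applied to the mass $a\,p$, which is then divided by the
*pre-step* parasite density (deliberately: the update reads pre-step
quantities throughout); a
consequence worth knowing is that $\sum a\,p$ is exactly conserved under
pure diffusion only when $p$ is spatially uniform (the conservation test
uses that configuration).  Mutation adds a per-cell Gaussian of standard
deviation $\sigma_a \sqrt{\Delta t} / \sqrt{\max(p, p_\mathrm{floor})}$:
the noise aggregates independent per-molecule mutation events, hence the
$1/\sqrt{p}$ scaling (large populations evolve slowly).  The floor
(`mut_floor`, default one density unit) caps the noise at the
single-molecule scale $\sigma_a\sqrt{\Delta t}$ in sparse cells; without
it the $1/\sqrt{p}$ amplification turns parasite-free cells into
white-noise generators whose affinity values instantly span the entire
clamp range, an artifact of the continuum description rather than
physics.  $\sigma_a$ itself has no canonical value in the parameter
table; the package default is 0.05, matching the half-width of the
microscopic model's mutation step ($\delta/2$).

**Affinity clamp.**  The affinity field is clamped to
`[a_min, a_max] = [0, 1]` by default so that the evolving-affinity runs
remain comparable with the microscopic model, whose replication
probability is a probability by construction.  The bounds are
parameters, and the distinction matters: the lattice affinity is a rate
constant, not a probability, and with `a_max = 1 = aR` (at equal decay
rates and $m=0$) the persistence inequality can never be violated, so
evolved parasites can at best neutralize, never overwhelm, the
replicases.  Raising `a_max` above `aR` lets selection push parasites
past the persistence threshold, which on large arenas produces the
collapse/recolonization wave regime and on small ones global extinction
(see Limitations).

## The agent simulator (`mas_*`, `run_mas()`)

The microscopic model represents each molecule as a circle of radius
`agent_size` on a periodic arena.  Per step: every agent's pre-sampled
remaining life time (RLT) is decremented and expired agents are removed;
agents are visited in random order; an agent overlapped by more than
`Nmax` others dies of crowding; survivors take a Brownian step
($\sqrt{2 D \Delta t}$ per axis) and then attempt one replication per
overlapping neighbor: parasite pairs are inert, replicase-parasite pairs
copy the parasite with its own probability $k_P$, replicase pairs copy
the partner with probability $k_R$.  Offspring appear at the template's
position, receive a fresh RLT, and a parasite offspring mutates with
probability $m_P$ by a uniform shift in $[-\delta/2, \delta/2]$ (clamped
to $[0,1]$).  Lifetimes are sampled as
$\mathrm{RLT} = \lfloor -\ln X / (d \Delta t) \rfloor + 1$, which is
geometric with success probability $1 - e^{-d\Delta t}$ and hence
statistically identical to per-step Bernoulli decay; the tests verify
both the closed form and, at the engine level, the implied exponential
survival curve and the $4 D \Delta t$ mean-squared-displacement law.

Conventions the pseudocode leaves open, fixed here once: the arena wraps
periodically (consistent with the lattice torus); overlap is strict
center distance $< 2\,$`agent_size`; in replicase-replicase encounters
the *visited neighbor* is the template (symmetric in distribution since
the neighbor list is shuffled); offspring can be reaction partners for
later-visited agents in the same step but are not themselves visited
until the next step; an agent may take part in several reactions in one
step; a partner removed earlier in the step (by crowding) is skipped.
Neighbor search uses a spatial hash with bins no smaller than the
interaction radius and is required by test to agree exactly with the
all-pairs computation.

## Shared metrics (`classify_outcome()`, `trace_statistics()`, `wave_condition()`)

A run ends `Alive` when both species are present at the time limit —
positive counts for agents, mean density above `extinction_eps`
(default $10^{-6}$) for the lattice.  `trace_statistics()` discards a
burn-in fraction (default 50%, because both simulators start from a
deliberately artificial uniform state) and reports extrema, mean, and a
period estimate from the mean spacing of autocorrelation peaks, flagged
undefined when no secondary peak reaches the prominence threshold.  The
traveling-wave persistence condition $\pi (v T)^2 \ge P$ — an expanding
front must cover the minimal regrowth area within one cycle — is
evaluated by `wave_condition()` on *measured* inputs; the model does not
predict $v$, $T$, or $P$ in closed form, so the package does not
pretend to derive them.

## Reproducibility and problem sizes

Both engines draw from a self-contained PCG32 generator seeded from the
configuration, so identical seeds give bit-identical runs regardless of
R's RNG state; this is what makes ~$10^{10}$ Gaussian draws per large
lattice run affordable.  The test suite runs at desk scale, chosen so
the whole suite stays in the minutes range: lattice checks use $1^2$ to
$128^2$ grids ($10^4$ to $2\times10^5$ steps), agent checks use $10^4$
molecules for the micro-laws and $400^2$ arenas with $500+500$ molecules
and 2000 steps for the survival/extinction grid (5 seeds per condition).
The ODE-limit cross-validation uses a moderate-density parameter set
($d_R = d_P = 0.3$, $m = 0.1$, $a_P = 0.5$, $\Delta t = 0.002$) rather
than the lattice defaults: at the defaults the equilibrium resource
density is $\sim 2\times10^{-4}$, the resource relaxation rate
$n_0/n^* \sim 5\times10^3$ makes forward Euler at $\Delta t = 0.1$
operate permanently in the resource-cap regime, and the discrete
stationary state then legitimately differs from the continuum one — a
property of the discretization itself, not a defect to paper
over, so the comparison is made where the discretization converges.

## What the synthetic runs do and do not show

Everything in this package is generated by the two simulators; there is
no external data.  The simulators emulate the paper-world of the model:
mass-action chemistry, free diffusion, unstructured molecules with a
single evolvable trait.  They do not emulate RNA sequences or folding,
replication complexes with finite duration, membranes, or 3D geometry.
Passing tests therefore demonstrate internal consistency between the
two observation scales and the closed-form analysis — not that real
prebiotic RNA populations behaved this way.

Known limitations:

* The full-scale wave phenomenology (affinity at a fixed point cycling
  in a band around 0.5 on a $1000^2$ lattice) is a large-arena effect:
  the collapse/recolonization cycle needs many out-of-phase local
  populations.  On desk-scale grids ($\le 256^2$) the same dynamics
  either stall near the affinity clamp (selection saturates at
  `a_max`), or, with the clamp lifted, synchronize and go globally
  extinct.  The package reports what its runs actually produce at the
  scale it runs them.
* The forward-Euler lattice scheme is only first-order accurate and its
  resource-cap branch activates at the default step size; treat the
  discrete system as the model when comparing with the continuum
  analysis.
* The agent engine's visit-order semantics make single-step outcomes
  order-dependent by construction; only
  distributional statements are meaningful.
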