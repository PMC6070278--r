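---
title: "Metabolic protocells: model, methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic protocells: model, methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protoflux)
```

## The model

A protocell is a vesicle containing `N` replicating catalytic sequences (the
*ploidy*) drawn from `g` functional types plus a defective type
$\omega$. Each functional type catalyses one irreversible reaction of a small
metabolic network; the production flux $\Phi$ of a single *critical
metabolite* M defines the protocell's fitness. Evolution couples three well
separated time scales: metabolic reactions (fastest, treated at steady
state), sequence replication and vesicle fission (the life-cycle), and
protocell population dynamics (slowest).

### Metabolic steady state

Catalysts follow irreversible Michaelis–Menten kinetics,
$v = k_{cat}[E][S]/(K_m + [S])$; concentrations are identified with counts
(no volume or dilution factor — a unit convention, since development never
dilutes the network in this model). Intermediates leak through the membrane
with permeability $\delta$ and are degraded outside. *Keystone* catalysts
consume a plentiful environmental input and run saturated at their limiting
velocity $k_{cat}[E]$.

For a unimolecular recycling motif fed an incoming waste flux $j$, the
steady state balance is $j = v + \delta [S]$ together with the rate law.
Eliminating $[S]$ gives the quadratic
$$ (v - j)(v - k_{cat}[E]) = \delta K_m v , $$
whose admissible root (the one with implied $[S] = (j-v)/\delta \ge 0$)
tends to $v = \min(j,\, k_{cat}[E])$ as $\delta \to 0$. A two-substrate
motif satisfies the analogous cubic and tends to
$\min(j_1, j_2, k_{cat}[E])$. Because the networks are feed-forward with
non-competing waste streams (each intermediate has one producer and at most
one consumer — competing consumption is rejected at validation rather than
modelled), whole-network fluxes compose motif by motif in topological order.
`network_flux()` implements the $\delta \to 0$ piecewise-linear calculus
used as fitness; `ode_steady_state_flux()` solves the leaky quadratics /
cubics exactly (or integrates the ODEs) as a numeric oracle.

**Sign note.** Writing the unimolecular balance as
$(v-j)(v-k_{cat}E) + \delta K_m v = 0$ — a form sometimes seen — is
inconsistent with the kinetic equations it is derived from: it would place
$v$ *between* $j$ and $k_{cat}E$, above the piecewise limit, with a negative
implied substrate concentration. The implementation uses the sign-consistent
form above; it agrees with direct numerical integration of the kinetics to
$10^{-7}$ and keeps the documented properties (velocity strictly below the
piecewise value, smooth peak lower than the sharp one, gap
$O(\sqrt{\delta K_m})$ at the kink).

**Root selection.** At finite $\delta$ the admissible root is the one
making every implied substrate concentration nonnegative; among candidates
the smallest admissible root is taken, which is the branch continuous with
the $\delta \to 0$ limit. $K_m$ defaults to 1 for every catalyst (it cancels
at $\delta = 0$) and the bimolecular interaction constants default to
$a_1 = a_2 = 1$ (the non-interacting reference case; no published values
exist for the alternatives).

### Built-in networks

Seven fixtures cover the published architectures. Their default parameters
are the ones used for the corresponding coexistence experiments
(`list_fixtures()` prints them):

* `keystone_recycler` — $\Phi = k_{cat}^\alpha a + c_M^\beta \min(c_w^\alpha
  k_{cat}^\alpha a,\, k_{cat}^\beta b)$. Default is the *near-boundary*
  kinetics ($k_{cat}^\beta = 2$, $c_M^\beta = 1.5$, peak at $\beta$
  frequency 1/3). The *far-boundary* variant is stated only as
  $c_w^\alpha = 2$ with "the remaining coefficients adjusted for equal
  maximum flux"; solving that condition analytically gives
  $k_{cat}^\beta = 1$, $c_M^\beta = 2$ (both variants peak at
  $\tfrac{5}{3}n$; the far peak sits at $\beta$ frequency 2/3).
* `serial3`, `parallel3` — one keystone with two recyclers in a chain or in
  parallel (all $k_{cat} = 1$, $c_M^\beta = c_M^\gamma = 4$). The serial and
  parallel fluxes follow the printed closed forms with unit waste
  stoichiometry (the serial flux is stated without $c_w^\alpha$; the
  fixtures follow the equations as printed).
* `bimolecular3` — two keystones whose wastes feed one bimolecular recycler
  ($c_M^\alpha = c_M^\beta = 2.5$, $c_M^\gamma = 4$).
* `serial4`, `parallel4`, `bimolecular4` — four-catalyst extensions built by
  the same composition rules (defaults $c_M = 6$ for every recycler; the
  high-benefit experiment overrides $c_M^\theta = 10$). The exact wiring of
  the four-catalyst networks is not published beyond the main-text
  description, so `bimolecular4` is constructed as the text prescribes: the
  parallel pair accepts the high-benefit fourth catalyst *as a bimolecular
  motif* joining the two secondary waste streams.

### The life-cycle

Development is `2N` independent samplings with replacement from the initial
contents: each draw copies functional type $i$ with probability
$q\,j_i/N$ and produces $\omega$ with probability $1 - q + q\,j_\omega/N$,
where $q$ is the replication accuracy (optionally $q = (1-\mu)^L$). Mutation
is applied per draw; back-mutation is structurally impossible, making
$\omega$ an irreversible sink. Assortment splits the `2N` sequences into two
daughters of `N` by multivariate hypergeometric sampling. The joint daughter
law factorises into two independent `N`-draw multinomials given the parent
(the Wright–Fisher factorisation), which the tests verify by brute-force
enumeration; the daughters are nevertheless dependent through the shared
developed state, which is why `sample_lifecycle()` returns both.

### Population dynamics

*Exact solver.* In the infinite-population limit the stationary frequencies
solve the eigen problem $\sum_j K(m|j) F(j) = \bar W F(m)$ with
$K(m|j) = \Phi(m)\,P_{WF}(m|j)$. `stationary_distribution()` uses power
iteration with $L_1$ normalisation; the residual is measured *relatively*,
$\|KF - \bar W F\|_1 / \bar W \le 10^{-12}$ (the kernel carries raw fluxes
of order $N k_{cat}$, so an absolute residual would be scale-dependent).
Start vector uniform; cap $10^5$ iterations; a flux that is identically zero
or a collapsed iterate raises an explicit error instead of silently
resolving a degenerate kernel. At `q = 1` the sink dimension is dropped by
default: $\omega$ is unreachable and keeping it makes the kernel reducible.
The lattice is refused above $10^5$ states (configurable), mirroring the
practical limit of the exact approach (ploidy up to ~100 with up to three
types); larger problems route to the agent-based solver.

*Agent-based solver.* `run_agent_based()` starts from `P` identical
protocells with `N` split evenly across the functional types (remainder to
the lowest-index types, $\omega = 0$). Each generation the population
develops and splits (doubling to `2P`), then `P` survivors are selected
without replacement with probability proportional to flux; fitness is
evaluated on the post-assortment daughter composition, matching
$K(m|j) = \Phi(m) P(m|j)$. If fewer than `P` daughters have positive flux
the run terminates with an extinction status. Defaults `P = 1000`,
`G = 5000` generations reproduce the published protocol; stationary
observables average the final 10% of generations (the source reports
stationarity at 5000 generations but no explicit averaging window).

**Selection scheme (a deliberate design choice).** "Selected without
replacement with probability proportional to fitness" admits two readings.
Successive weighted draws (equivalently exponential-key order statistics)
seem natural, but when exactly *half* of a pool must be kept they give
saturating inclusion probabilities $1 - e^{-w_i \tau}$: selection
differentials are compressed, and the large-`P` limit is *not* the eigen
equation. This is measurable — for the two-catalyst fixture at `N = 20`,
`q = 1` the successive-draw fixed point has coexistence 0.8105 versus
0.8992 for the eigen solution, and agent-based runs up to `P = 16000`
confirm it. Since the model's defining property is that the agent-based
algorithm approaches the infinite-population eigen limit, the package
selects survivors by randomised systematic probability-proportional-to-size
sampling: inclusion probability exactly `count * w_i / sum(w)` (clamped at
1 with the excess redistributed), without replacement. With this scheme
`P = 1000` runs agree with the exact solver within Monte-Carlo error.
`select_half_without_replacement()` exposes both schemes;
`method = "successive"` reproduces the compressed-selection variant.

### Observables

* **Coexistence fraction** — population mass on protocells carrying at
  least one copy of *every* functional type. One copy is the weakest
  reading of "containing the maximum number of functional sequence types";
  the threshold is configurable but defaults to 1. $\omega$ never
  disqualifies.
* **Mean flux** — for the exact solver this is the stationary mean fitness
  $\sum_j \bar w(j) F(j)$ with $\bar w(j) = \sum_m \Phi(m) P(m|j)$, which
  equals the leading eigenvalue $\bar W$ (an identity the tests check to
  $10^{-8}$). Note that averaging $\Phi$ over the post-selection survivors
  is a *different*, selection-biased quantity,
  $E_G[\Phi^2]/E_G[\Phi] \ge \bar W$; it is exposed as an attribute but is
  not the $\bar W$ analogue. The agent-based `mean_flux()` correspondingly
  averages the pre-selection daughter pool.
* **Defective frequency** — $E[m_\omega]/N$.
* **Ternary projection** — three selected type axes renormalised per
  composition, weighted by stationary mass; compositions with all three
  selected counts zero are flagged undefined and their mass reported
  separately.

`scan_observables()` drives (N, q) grids with either solver, derives one
seed per agent-based replicate from the master seed by a fixed affine map,
records per-point failures without aborting the scan, and can cache
completed points on disk as JSON.

## What the tests do and do not establish

The stochastic suite is fully seeded, hence deterministic. The acceptance
suite checks, at the published parameter values: exact agreement of the
composed fluxes with their closed forms; linear convergence of the leaky
motif roots to the piecewise limit; exact normalisation and factorisation
of the life-cycle distributions (brute-force enumeration at small `N`);
eigen-solver correctness against a dense decomposition; exact-vs-agent
agreement within 3 Monte-Carlo standard errors at `P = 1000`, `G = 5000`;
the kinetics/boundary orderings of the coexistence curves; the development
ODE invariants; and neutral-drift fixation probabilities. The agent-based
*ordering* experiments for the three- and four-catalyst architectures run
at reduced scale (G = 1500–2000, 2–3 replicates instead of G = 5000) to fit
a test-time budget; at the tested grid points the orderings are far outside
Monte-Carlo error except where both curves saturate near 1, where the
assertion is made within 3 standard errors of the difference.

A neutral-drift subtlety: "recycler benefit set to zero" is realised with
the two-keystone network (`bimolecular3`) and no recycler copies, so that
$\Phi = 2.5(a+b)$ is constant and the keystone split drifts neutrally —
with the *single*-keystone network, zeroing the recycler's benefit makes
the recycler strictly deleterious instead, and fixation probability would
not equal initial frequency.

These are all properties of the stated model world. The synthetic dynamics
emulate idealised vesicles: no volume growth, no catalytic trade-offs, no
fusion or recombination, perfectly non-competing reactions, and constant
environmental inputs. Green tests establish internal correctness of the
solvers and the published orderings under those assumptions, not the
behaviour of real vesicle chemistry.

## The development oracle

`simulate_development()` integrates the full replication–metabolism ODEs
(mass-action replication at rate `r`, $d[M]/dt = \Phi - r[M]\sum_i [E_i]$,
leaky Michaelis–Menten intermediates) with an embedded Dormand–Prince 5(4)
integrator written for this package (no ODE solver package is assumed;
relative tolerance $10^{-9}$ by default). It exists solely to verify the
time-scale-separation facts that justify replacing explicit development
with `2N` samplings: the type ratio $x$ is a conserved quantity
($dx/dt = 0$, checked to $10^{-6}$), and for
$k_{cat}/r \ge 10^3$ the pool grows asymptotically at the scaled flux
$\phi = \Phi/\sum_i[E_i]$ (checked to 1%). The evolutionary model never
calls this module. $K_m$ values for development runs are unstated in the
source; the module uses the metabolism default $K_m = 1$.

## Known limitations

* The exact solver stores a dense kernel: memory is $O(L^2)$ in the lattice
  size, which is what limits it to small ploidy / few types.
* The bimolecular leaky cubic assumes a common permeability for its two
  substrates (true of every fixture); distinct permeabilities are averaged.
* Power iteration reports failure on non-convergence but does not detect a
  genuinely degenerate leading eigenspace beyond the zero-flux case.
* The Moran-process and branching-process formulations (whose equilibria
  coincide with the eigen equation) are not implemented, nor are fusion,
  recombination, chromosomal linkage, or catalytic trade-offs.

## A worked example

```{r example, eval = FALSE}
net <- network_fixture("keystone_recycler")
p <- lifecycle_params(N = 20, q = 1, g = 2)
st <- stationary_distribution(build_kernel(net, p))
coexistence_fraction(st)   # 0.8992365
st$W_bar                   # 25.92571

ab <- run_agent_based(net, p, pop_size = 1000, generations = 5000, seed = 1)
coexistence_fraction(ab)   # 0.89768
mean_flux(ab)              # 25.8903
```
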