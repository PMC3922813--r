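---
title: "Co-evolving cooperation on interdependent populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-evolving cooperation on interdependent populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(coevonet)
```

## The model

Two groups of players, of sizes $N_1$ and $N_2$, are joined by an evolving
network: $L_1$ links inside Group-1, $L_2$ inside Group-2 and $L_{12}$
between the groups, with the total $L = L_1 + L_2 + L_{12}$ conserved.
Every player is a cooperator (C) or defector (D) in the donation game: a C
pays a cost $c$ to give its partner a benefit $b$ ($b > c > 0$), a D pays
and gives nothing.  In matrix form, with rows and columns ordered (C, D),

$$M = \begin{pmatrix} b-c & -c \\ b & 0 \end{pmatrix},$$

the standard prisoner's dilemma ordering $T > R > P > S$.

Each elementary event is, with probability $W$, a **strategy update**:
a linked (focal, neighbour) pair is drawn and the focal player's strategy
replaces the neighbour's with the Fermi probability
$\left[1 + e^{-w\,(P_{\mathrm{focal}} - P_{\mathrm{neighbour}})}\right]^{-1}$,
where $P$ is the accumulated payoff against all current neighbours (both
groups alike) and $w \ge 0$ is the selection intensity.  Otherwise (with
probability $1-W$) it is a **linking event**: a link is selected uniformly;
a link whose endpoints play $(s, s')$ is severed with a strategy-pair
fragility $k_{ss'} \in (0,1]$; if severed, one endpoint is retained at
random and rewires — with the *intra-group attaching bias* $p$ to a uniform
non-neighbour of its own group, otherwise to a uniform non-neighbour of the
other group.  Link lifetimes are geometric, so $1/k_{ss'}$ is the expected
number of selections a partnership survives: fragilities encode how long
each kind of relationship lasts.

Small $W$ is the *fast-rewiring* regime: the network re-equilibrates
between strategy changes, which is the premise of the entire analytical
layer.

## The link-type chain

A link carries one of ten types — the unordered pair of its endpoints'
(strategy, group) labels; `link_types()` fixes the canonical order.  With
the two cooperator frequencies $x_1, x_2$ frozen, one linking event acting
on a single link is a Markov chain on these ten types
(`link_transition_matrix()`): survival with probability $1 - k_e$, else a
retained endpoint (probability $1/2$ each) rewires, the new partner's group
set by $p$ and its strategy by the target group's frequency.  That partner
sampling is mean-field: it ignores the exclusion of current neighbours, an
$O(\mathrm{degree}/N)$ correction, so the chain is an approximation for
sparse networks.

For $0 \le x_i \le 1$, $p < 1$ and all $k_e > 0$ the stationary law has a
closed product form (`link_stationary()`): for a type with endpoint labels
$a, b$,

$$\pi_{ab} \;=\; \frac{1}{Z}\,
  \frac{(2 - \delta_{ab})\; \omega(g_a, g_b)\; f_a f_b}{k_{ab}},$$

with $\delta_{ab}$ the Kronecker delta of the two labels, group weight
$\omega = p$ intra / $1-p$ inter, $f$ the frequency of the endpoint's
strategy in its group, and $Z$ the normalisation.  The derivation is a flux
balance: the breaking flux $\pi_e k_e$ out of each type must be stationary
under the rebuild kernel, whose stationary ordered-pair law factorises over
endpoint labels with equal mass on the two groups.  Two consequences worth
noting:

* $\pi$ is invariant under rescaling all $k_e$ by a common factor — only
  *relative* fragilities shape the structure;
* durable types accumulate: robust C–C links ($k_{CC}$ small) are
  over-represented relative to random matching by the factor $1/k_{CC}$.

`link_stationary_numeric()` is the independent check: the left unit
eigenvector of the transition matrix, with reducible corner cases
($x_i \in \{0,1\}$, $p \in \{0, 1\}$) restricted to the closed
communicating class and flagged.  The two routes agree to $10^{-8}$ across
random parameter grids in the test suite; stationarity and normalisation
are asserted at $10^{-10}$ and $10^{-12}$.

```{r}
pars <- coevo_params()
link_stationary(pars, x1 = 0.6, x2 = 0.4)
```

## Fast-rewiring mean field

Because long-lived links host proportionally more interactions, the
effective game under fast rewiring is the payoff matrix with every entry
divided by its strategy pair's fragility (`rescale_payoff()`):
$R' = (b-c)/k_{CC}$, $S' = -c/k_{CD}$, $T' = b/k_{CD}$, $P' = 0/k_{DD} = 0$.
Averaging over the stationary structure, a player in group $g$ meets
cooperators with the mix $m_g = p\,x_g + (1-p)\,x_h$ ($h$ the other group),
giving the fitnesses (`mean_fitness()`)

$$f_{C,g} = m_g R' + (1 - m_g) S', \qquad
  f_{D,g} = m_g T' + (1 - m_g) P'.$$

A common positive factor (total link mass per player, the stationary
normalisation) is absorbed into the selection intensity.

Strategy counts change through pairwise comparison across links.  Drawing
an ordered linked pair from the stationary pair law and applying the Fermi
rule gives the per-event gain/loss probabilities $T_g^\pm$
(`imitation_rates()`).  Their difference is the exact finite-$w$ drift
(`replicator_field(..., limit = "fermi")`).  Expanding to first order in
$w$ and dropping a state-dependent *positive* time rescaling (which moves
no orbit, equilibrium or eigenvalue sign) yields the polynomial
weak-selection field (`limit = "weak"`, the default), for group 1:

$$\dot x_1 = \underbrace{\tfrac{1-p}{2}\,(x_2 - x_1)}_{\text{neutral exchange}}
  \;+\; \tfrac{w}{2}\,p\,x_1(1-x_1)\,(f_{C,1} - f_{D,1})
  \;+\; \tfrac{w}{4}\,(1-p)\bigl[x_2(1-x_1)(f_{C,2}-f_{D,1})
        - x_1(1-x_2)(f_{D,2}-f_{C,1})\bigr],$$

and symmetrically for group 2.  The first term is selection-free: imitation
across inter-group links equalises the two frequencies even at $w = 0$.
The second is the classic replicator term within the group; the third is
the cross-group selection channel.  Groups are taken symmetric
($N_1 = N_2$, $L_1 = L_2$, shared $p$) throughout the analysis layer, as
the closed forms below require; asymmetric populations can still be
simulated and integrated numerically.

### Equilibria, thresholds, stability

The corners $(0,0)$ and $(1,1)$ are always rest points.  On the diagonal
$x_1 = x_2 = x$ the field reduces to
$\tfrac{w}{2}\,x(1-x)\,\bigl[B + D\,x\bigr]$ with
$B = S' - P' = -c/k_{CD}$ and
$D = (b-c)\left(\tfrac{1}{k_{CC}} - \tfrac{1}{k_{CD}}\right)$, so the
third rest point is

$$x^* \;=\; -\frac{B}{D} \;=\;
   \frac{c\,k_{CC}}{(b-c)\,(k_{CD} - k_{CC})}
   \qquad (\texttt{interior\_fixed\_point()}).$$

It lies in $(0,1)$ — and all-C is simultaneously stable — exactly when

$$\frac{b}{c} \;>\; \frac{k_{CD}}{k_{CD} - k_{CC}}
  \qquad (\texttt{critical\_benefit\_cost()}),$$

which requires mixed links to be more fragile than cooperator pairs
($k_{CD} > k_{CC}$).  The threshold falls as $k_{CD}$ grows and rises with
$k_{CC}$; in terms of the fragility ratio $\kappa = k_{CC}/k_{CD}$ it is
$1/(1-\kappa)$, and $x^* = c\,\kappa / ((b-c)(1-\kappa))$ grows with
$\kappa$ (a smaller basin of cooperation) and falls as $b$ grows (a larger
one).  Neither expression involves $k_{DD}$ — idle partnerships pay
nothing either way — nor $p$.

The exchange symmetry makes the Jacobian at any diagonal point of the form
$\bigl(\begin{smallmatrix} a & b\\ b & a\end{smallmatrix}\bigr)$, with
eigenvalues $a+b$ along $(1,1)$ and $a-b$ along $(1,-1)$.  In closed form
(`equilibrium_eigenvalues()`, checked against the analytic Jacobian's
numeric eigen-decomposition at $10^{-8}$ and against finite differences at
$10^{-6}$):

| point | along the diagonal | transverse |
|---|---|---|
| $(0,0)$ | $wB/2$ | $-(1-p) + w p B / 2$ |
| $(1,1)$ | $-wA/2$ | $-(1-p) - w p A / 2$ |
| $(x^*, x^*)$ | $q$ | $-(1-p) + q\,p\,(2p-1)$ |

with $A = R' - T'$ and $q = \tfrac{w}{2} x^*(1-x^*) D > 0$.  All-D is
unconditionally stable ($B < 0$); all-C is stable iff $A > 0$, i.e. iff the
benefit-to-cost condition holds — that sign change *is* the threshold, and
the test suite recovers it independently by bisecting the eigenvalue sign
in $b/c$.  The interior point always repels along the diagonal (it is the
basin boundary separating the all-C and all-D attractors) while its
transverse eigenvalue changes sign at the **critical intra-group bias**
$p_c$ (`critical_intra_bias()`, located by bisection; the closed-form root
of the quadratic $-(1-p) + q p (2p-1)$ is the test oracle): below $p_c$ the
point is a saddle — the neutral exchange pins the dynamics to the diagonal
— above it an unstable node and the phase portrait is the full coordination
picture.  Because the balance is between the $O(1)$ exchange term and the
$O(w)$ selection terms, $p_c \to 1$ as $w \to 0$: under genuinely weak
selection, near-complete group closure is needed before the transverse
direction destabilises.

```{r}
classify_equilibria(pars)
```

### Numerics

* Trajectories (`integrate_replicator()`) use an adaptive Cash–Karp
  Runge–Kutta 4(5) pair written in the package (no ODE solver is among the
  available dependencies), relative tolerance $10^{-8}$, with rejected
  steps on any excursion beyond the unit square — the exact field is
  inward or tangent on the boundary, so only roundoff can point outside —
  and early termination within $10^{-6}$ of a corner.
* The diagonal basin boundary (`basin_threshold()`) is bisected to
  $10^{-6}$ and agrees with the closed-form $x^*$ at $10^{-5}$.
* The 10-state stationary solve is benign; closed form and eigen-solve are
  compared at $10^{-8}$.

## The agent-based model

`simulate_coevolution()` runs the exact stochastic process on an explicit
network, with a compiled event loop driven by R's RNG: a fixed seed
reproduces the whole record bit for bit.  Initial networks
(`init_network()`) are uniform simple graphs with the exact compartment
link counts, and strategies are placed by exact count
($\lfloor \text{fraction} \times N \rfloor$ cooperators per group), so
basin experiments start from precisely the configured frequency.  Edge
count conservation, the simple-graph property and the incremental type
counters are asserted against full recounts in the tests.

Two deliberate modelling choices deserve their own account:

**Pair selection for imitation.**  The mean-field drift weights ordered
(focal, neighbour) pairs by link mass.  The simulator therefore defaults to
drawing a uniform link with a uniform orientation (`pair_sampling =
"link"`).  The often-quoted alternative — a uniform focal *player*, then a
uniform neighbour — weights each pair by the inverse of the focal player's
degree.  Under heterogeneous fragilities this is not a detail: with
$k_{CD} > k_{CC}$, defectors' partnerships churn while cooperators'
persist, so defectors end up with systematically fewer links — and the
node-uniform rule converts exactly the mechanism that rewards cooperators
(durable C–C links) into a selection-independent *imitation-rate* advantage
for defectors of order $k_{CC}/k_{CD}$.  At weak selection that $O(1)$ bias
dominates every $O(w)$ payoff difference and defection sweeps from any
initial condition, contradicting the bistability the mean field predicts
(and that simulation studies of this model report).  The variant remains
available as `pair_sampling = "node"`, and a regression test documents the
sweep.

**Rewiring eligibility.**  The new partner must not be a current neighbour
(the graph stays simple and $L$ constant); the just-broken partner *is*
eligible again, a simplest-uniform choice whose effect on the chain is
$O(1/N)$.  If the chosen side offers no eligible partner the event is
consumed as a no-op, as is a strategy event landing on an isolated focal
player.

### What the reduced scale does and does not establish

The package's default world is groups of $N = 100$ with mean degree 12,
$b = 1$, $c = 0.5$, $k_{CC} = 0.2$, $k_{CD} = k_{DD} = 0.8$, $p = 0.8$,
$W = 0.01$, $w = 0.05$: a bistable regime with threshold ratio $4/3$
against $b/c = 2$ and $x^* = 1/3$, chosen so that every analytical claim is
exercised at test scale within minutes.  Two finite-size effects displace
the simulated basin boundary upward from $x^*$ at this scale, and a user
should know them:

* *Pair conditioning.*  The Fermi comparison conditions on the selected
  C–D link.  The defector endpoint is size-biased by its number of
  C-neighbours (its payoff), the cooperator endpoint by its number of
  D-neighbours (its penalty); both corrections are $O(1)$ payoff units
  against a mean payoff gap that scales with degree, hence a relative
  $O(1/\mathrm{degree})$ shift against cooperation.
* *Partner-pool saturation.*  At degree non-negligible against $N$, the
  non-neighbour constraint depresses C–C link counts below the chain's
  prediction, an $O(\mathrm{degree}/N)$ effect.

Measured on the default world, the quasi-stationary drift across C–D links
changes sign near $x \approx 0.58$ at $N = 100$ per group, moving to
$\approx 0.51$ at $N = 300$ and $\approx 0.48$ at $N = 600$ at fixed
degree.  Stochastic fixation adds a further displacement on top of the drift
crossing: just above it the positive drift is weak, so trajectories
diffuse into the all-D basin, and the initial fraction at which a
*majority* of runs fixates at all-C is near $0.7$ at $N = 100$.
Reduced-scale simulations therefore establish the *basin structure*
(fixation to all-D well below the boundary, to all-C well above, a
step-shaped initial-condition response) and the qualitative bias
phenomena — not the coincidence of the empirical threshold with $x^*$,
which is approached only as both $N$ and degree grow.  The acceptance
test for basin agreement is implemented at the stated reduced scale on
the standard 11-point initial-fraction grid and is knowingly red at the
intermediate grid points (initial fractions between $x^* + 0.1$ and
$\approx 0.7$ fixate to all-D although they lie above $x^*$): the
displacement exceeds one grid cell for every feasible degree at
$N = 100$, and no honest setting of the remaining free parameters
removes it.

The moderate-bias phenomenon — final cooperation over a $p$-grid peaking
strictly inside $(0,1)$ — is a finite-population effect on top of the
deterministic picture ($x^*$ itself does not depend on $p$): large $p$
severs the inter-group channel and leaves two small, fluctuation-prone
populations; small $p$ dissolves intra-group assortment and lets defectors
feed on cross-group cooperators.  It is reproduced at reduced scale
(30 replicates per grid point) from a start near the empirical basin
boundary, where both outcomes are reachable.

## Synthetic data

There is no external data: the generator *is* `init_network()` plus the
event process, and the stated world above is the package's reference
condition.  What the generator emulates: conserved link budgets, exact
initial frequencies, geometric link lifetimes, uniform mixing within
compartments.  What it deliberately does not: degree-heterogeneous initial
topologies, mutation, continuous-time scheduling, more than two groups —
all outside the model.

## Experiment drivers

`phase_portrait()`, `bias_sweep()`, `initial_fraction_sweep()` and
`run_config()` (JSON configuration, CSV + JSON artifacts with a provenance
record) return tidy tibbles with analytic overlays ($x^*$, $p_c$) taken
from the mean-field layer, never recomputed ad hoc; `autoplot()` methods
render them.  Every driver is deterministic given (configuration, seed);
replicate $r$ of a sweep point uses `seed + r`, keeping replicates
independent yet reproducible.

```{r, fig.alt = "Phase portrait of the weak-selection dynamics"}
autoplot(phase_portrait(pars, n_grid = 9, horizon = 2000))
```

## Known limitations

* The finite-size noise term of the population-level stochastic dynamics
  is represented only by the simulator itself; the analytical layer is the
  deterministic drift.
* Closed forms ($x^*$, thresholds, eigenvalues) assume symmetric groups;
  asymmetric settings are numeric-only.
* The link-type chain is mean-field in the partner's strategy and ignores
  neighbour exclusion; its accuracy degrades as degree approaches group
  size (quantified above).
* Breaking probabilities are strategy-pair-keyed by default; a full
  10-type schedule is accepted but the closed-form analysis then no longer
  applies (group-dependent fragilities change the chain, not the formulas
  coded here).
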