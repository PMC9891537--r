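---
title: "Modelling ligand-dimer cis-inhibition of Notch signalling"
author: "notchdimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ligand-dimer cis-inhibition of Notch signalling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notchdimer)
```

## The model family

Juxtacrine Notch signalling is governed by a balance of three interactions:
*trans-activation* of the receptor by ligand presented on neighbouring cells,
*cis-inhibition* by ligand in the same cell, and the weaker *cis-activation*
by same-cell ligand. Biochemical evidence indicates that Notch ligands such
as DLL4 self-associate through a membrane-proximal EGF-like repeat, and that
this dimerization is specifically required for cis-inhibition while
monomeric ligand remains fully competent for trans-activation. This package
implements a deterministic mass-action ODE family built around that
distinction.

Each cell tracks ligand monomers $L$, ligand dimers $L^{*}$, receptors $N$
and free Notch intracellular domain $S$ (the pathway's signal, and the
quantity we call "Notch activity" throughout). The general model is

$$
\begin{aligned}
\dot L      &= b_L - \beta L - 2 k_d L^2 - k_1 N_{ext} L - k_3 N L - k_5 N L,\\
\dot L^{*}  &= k_d L^2 - \beta L^{*} - k_2 N_{ext} L^{*} - k_4 N L^{*}
              - k_6 N L^{*},\\
\dot N      &= b_N - \beta N - (k_1 L_{ext} + k_2 L^{*}_{ext} + k_3 L
              + k_4 L^{*} + k_5 L + k_6 L^{*})\,N,\\
\dot S      &= (k_1 L_{ext} + k_2 L^{*}_{ext} + k_5 L + k_6 L^{*})\,N
              - \beta_S S,
\end{aligned}
$$

where $L_{ext}$, $L^{*}_{ext}$ and $N_{ext}$ are the levels presented by
neighbouring cells. The six interaction rates select a hypothesis: $k_1/k_2$
trans-activation by monomers/dimers, $k_3/k_4$ cis-inhibition by
monomers/dimers, $k_5/k_6$ cis-activation by monomers/dimers. Every named
configuration in the package (`set_interactions()`) is a parameter
assignment on $k_1..k_6$, never a separate code path:

* cis configurations C1/C2/C3 (dimer / monomer / both cis-inhibition),
* trans configurations T1/T2/T3 (monomer / dimer / both trans-activation),
* cis-activation scenarios 1/2/3 (monomer / dimer / both, isolated cells).

Two reductions have closed-form steady states. With $k_d = 0$ and
monomer-only interactions the system collapses to the classical
*mutual-inactivation* (MI) model (`rhs_mi()`); the favoured
*ligand-dimerization model T1* keeps $k_1 = k_t$ (monomer trans-activation)
and $k_4 = k_{ci}$ (dimer cis-inhibition) only (`rhs_t1()`). Extensions
cover homogeneous oligomer populations of size $n$ (`rhs_oligomer()`, with
monomer drain $n k_d L^n$ and oligomer gain $k_d L^n$) and a
cytoplasm/membrane split (`rhs_compartment()`) in which dimerization and
dimer cis-inhibition are cytoplasmic, activation happens at the membrane,
and transport runs at $k_r$.

### Modelling assumptions

* Deterministic, continuous amounts (molecules per cell), time in hours; no
  stochasticity anywhere.
* Dimerization is irreversible as written: there is no dimer-dissociation
  term in the equations, so none is implemented.
* Degradation is first-order and identical ($\beta$) for all ligand and
  receptor pools; the released intracellular domain decays faster
  ($\beta_S$).
* No transcriptional feedback of $S$ onto the production rates, no delays,
  no ligand hetero-dimers.
* Negative states or rates are rejected with an error rather than clamped;
  silent clamping would mask integration bugs. (The ODE drivers clamp only
  sub-tolerance solver excursions.)

## Parameters

| name | meaning | default | units |
|------|---------|---------|-------|
| `b_L`, `b_N` | ligand / receptor production | 200 | molecules h⁻¹ |
| `k_d` | ligand oligomerization rate | 1e-4 | molecules⁻⁽ⁿ⁻¹⁾ h⁻¹ |
| `k_t` | trans-activation rate | 5e-5 | molecules⁻¹ h⁻¹ |
| `k_ci` | cis-inhibition rate | 6e-4 | molecules⁻¹ h⁻¹ |
| `k_ca` | cis-activation rate | 5e-6 | molecules⁻¹ h⁻¹ |
| `beta` | ligand/receptor degradation | 0.1 | h⁻¹ |
| `beta_S` | signal degradation | 0.5 | h⁻¹ |
| `k_r` | cytoplasm→membrane transport | 0.1 | h⁻¹ |
| `n` | oligomer size | 2 | — |

The defaults reflect the simulation baseline: a protein half-life of about
7 hours ($\ln 2/\beta$), a rapidly decaying signal, production rates giving
a few thousand molecules per cell, and interaction rates at the order of
magnitude typical of per-molecule protein–protein association in this
pathway. Cis-activation is roughly an order of magnitude weaker than
trans-activation, and it is *always ignored when trans-presented ligand is
present* — that convention is enforced by the scenario builders
(`production_sweep()`, `oligomer_sweep()`, …), not by the right-hand sides.

## Closed-form steady states and root selection

For the MI model with effective clearances $\beta_1 = \beta + k_t N_{ext}$
and $\beta_2 = \beta + k_t L_{ext}$, the ligand steady state is the positive
root of a quadratic,
$\bar L = B + \sqrt{B^2 + \beta_2 b_L/(\beta_1 k_{ci})}$ with
$B = (b_L-b_N)/(2\beta_1) - \beta_2/(2 k_{ci})$. For T1, the monomer
equation decouples (monomers are not cis-inhibited), giving
$\bar L = \sqrt{(\beta_1/4k_d)^2 + b_L/2k_d} - \beta_1/4k_d$ — notably
independent of $b_N$ — and the dimer level solves an analogous quadratic.
Three numerical choices matter:

* **Root branch.** Both quadratics have one non-negative root for positive
  parameters; only the "+" branch is ever returned.
* **Stable evaluation.** When the linear coefficient is large the textbook
  "+"-root form cancels catastrophically; we use the standard rewrite
  $C/(\sqrt{B^2+C}-B)$ for $B<0$.
* **Receptor level.** The receptor follows from the production balance,
  $\bar N = b_N/(\beta_2 + k_{ci}\bar L)$ (MI) and
  $\bar N = b_N/(\beta_2 + k_{ci}\bar L^{*})$ (T1). These are algebraically
  identical to the difference forms
  $(\beta_1\bar L - (b_L-b_N))/\beta_2$ and
  $(\beta\bar L^{*} - (k_d\bar L^2 - b_N))/\beta_2$ — we verified the
  identity by summing the steady-state balances, and the tests assert it
  numerically — but immune to cancellation in the mutually-exclusive regime
  where $\bar N \to 0$.

In the strong-cis-inhibition limit the MI model is *mutually exclusive*: a
cell is either a sender ($\bar L \approx (b_L-b_N)/\beta_1$,
$\bar N\approx0$) or a receiver ($\bar N \approx (b_N-b_L)/\beta_2$). T1
behaves differently: when $b_N > k_d\bar L^2$ the receptor coexists with a
high monomer pool, $\bar N \approx (b_N - k_d \bar L^2)/\beta_2$; when
$b_N < k_d\bar L^2$ the dimers titrate the receptor away
(`t1_receptor_limit()`). This coexistence is exactly what dorsoventral
boundary patterning requires (below).

```{r}
t1_steady_state(notch_params())
```

## Numerics

* **Trajectories** (`simulate_cell()`): adaptive Dormand–Prince 4(5)
  (`deSolve`'s `ode45`), relative tolerance 1e-8, absolute tolerance 1e-10.
  Excursions below $-100\times$`atol` abort with an error; smaller ones are
  clamped to zero.
* **Fixed points** (`steady_state_numeric()`): `lsoda` integration in
  chunks scaled to the slowest clearance time ($10/\beta$), declared
  converged when the maximum relative state change over a trailing 10 h
  window falls below 1e-8 (both window and tolerance are arguments), then
  polished by damped Newton iteration with a forward-difference Jacobian.
  The returned state must zero the equations to 1e-8·max($b_L$, $b_N$, 1);
  non-convergence within $t_{max}=10^5$ h raises an error carrying the last
  state and residual. Sweeps start from an empty-ligand state
  ($L=L^{*}=0$, $N=b_N/\beta$), which avoids the stiff transient a
  ligand-loaded initial guess would create under strong dimerization.
* **Tissues** (`simulate_tissue()`): the whole lattice is integrated as one
  coupled system (no per-cell relaxation sweeps, so results cannot depend
  on a cell-update order) with `lsoda`, which switches to a stiff method
  when the large dimer pools make the system stiff; steady state is
  declared when every equation's residual is below 1e-6·max($b_N$).
* Ties in sweep peak detection are avoided by construction: non-monotonicity
  is asserted as "the grid argmax is interior", never by comparing
  near-equal values.

## Scenario conventions

* A single receiving cell exposed to fixed trans ligand uses
  $L_{ext} = 1500$ molecules (the package-wide convention for the
  fixed-trans setting).
* **Trans sweeps** solve sender and receiver as one coupled 8-ODE system —
  the receiver's $L_{ext}$ is the sender's own steady-state monomer level
  and vice versa — rather than equating the swept production rate with
  $L_{ext}$ directly, because trans exposure is defined by neighbour ligand
  *levels*, not production rates. Whether the sending cell also expresses
  receptor is exposed as `N_ext`/`b_N` configuration, defaulting to a
  receptor-bearing identical sender.
* **Two identical cells** exchange $L_{ext} = $ the partner's $L$ (and
  $L^{*}_{ext}$ when dimer trans-activation is active); identical cells
  remain exactly symmetric, which the tests assert.
* The **cis-inhibition relief** time course starts from a dimer-loaded
  state $(L, L^{*}, N, S) = (500, 9500, 0, 0)$ molecules with ligand
  production switched off and constant trans exposure; the unprinted
  conventions for that run default to $L_{ext}=1500$ and $b_N=200$ and are
  config-overridable.

## The tissue model

The lattice is a rectangular grid (default 20×20) with a von Neumann
4-neighbourhood, switchable to Moore (8) or hexagonal (6); the biological
claims do not depend on the topology and the tests check the boundary
patterns on all three. The trans input of a cell is the arithmetic mean of
its neighbours' ligand monomers (boundary cells average over existing
neighbours only), and symmetrically each cell's ligand sees the mean
responsive receptor of its neighbours.

Two patterning systems are built in:

* **Wing vein** (`wing_vein_simulation()`): a single ligand with the
  exponential production gradient $b_L(y) = L_{max} e^{-|y-y_0|}$
  ($L_{max} = 15000$ molecules/h at the centre) and uniform $b_N = 200$.
  The high-ligand centre cis-inhibits itself and signals to its flanks,
  producing two parallel bands of activity with a trough at the centre.
* **Dorsoventral boundary** (`dv_boundary_simulation()`): dorsal rows
  produce Serrate, ventral rows Delta ($b_L = 200$), receptor is uniform
  ($b_N = 1000$). Fringe glycosylation is modelled as *binary gating*:
  Notch in dorsal cells can only be trans-activated by Delta, ventral Notch
  only by Serrate (graded affinities would be a configuration extension).
  The two ligand species evolve independently by the T1 equations; the
  receptor equation sums cis-inhibition over species and trans terms over
  the species its compartment responds to. This is the minimal two-species
  extension consistent with the single-species model; hetero-dimers are
  deliberately excluded. Dorsal Delta expression, reported in vivo but
  non-functional, is off by default and available as a configuration.
  Ectopic expression stripes reuse the exponential profile, are oriented
  parallel to the boundary with a configurable centre, and may carry their
  own dimerization rate (implemented as an independently parameterized
  ligand species with the same gating), which is how the low-dimerization
  ectopic-ligand experiment is expressed.

Under T1 the boundary rows signal strongly in both directions while the
MI model, which cannot hold ligand and receptor in the same cell at these
production rates, produces no boundary enrichment. Decreasing $b_N$ toward
the ligand production rate extinguishes the boundary signal.

**Problem sizes.** The package defaults to 20×20 lattices; the shipped
figure presets and the test suite use 17×8 (wing vein) and 12×6
(dorsoventral) grids, which are already several ligand decay lengths wide
in the patterning direction — the gradient falls by $e$ per row, so the
patterns of interest occupy a handful of rows and the qualitative claims
are insensitive to further enlargement.

## Sensitivity analysis

`sensitivity_scan()` perturbs one parameter at a time over the fold grid
{0.1, 0.2, 0.5, 1, 2, 5, 10} in three reference settings (fixed-trans
receiving cell, two identical cells, isolated cis-activating cell) and
summarizes each parameter by the local log–log sensitivity
$|\mathrm{d}\log \bar S / \mathrm{d}\log\theta|$, estimated by a central
difference at fold 1 (evaluations at 0.95× and 1.05×). The perturbation
range and index definition are package choices (nothing canonical exists),
both overridable. Structural checks: the index of $\beta_S$ is exactly 1
in every setting ($\bar S \propto 1/\beta_S$); $k_t$ is exactly inert in
the contact-free setting; an identically zero baseline activity makes the
index undefined and is reported as `NA`.

## What the simulations do and do not show

All inputs are synthetic by construction — the package simulates model
cells, not measured ones. The study conditions (baseline rates, the 1500
molecule trans exposure, the dimer-loaded initial state, the gradient peak
of 15000 molecules/h, compartment production rates) define idealized
versions of the corresponding experiments. Consequently:

* Passing tests demonstrate the *internal* claims — reductions between
  model variants, closed forms against independent numerics, and the
  qualitative shapes of dose–response curves and tissue patterns — not
  agreement with any quantitative measurement.
* Real reporter data live in arbitrary units and cannot parameterize these
  equations; the package therefore replicates published dynamics and
  patterns qualitatively only.
* The lattice omits growth, division, movement, mechanics and Fringe enzyme
  kinetics; compartment boundaries are static labels.

## Known limitations

* No closed forms exist (or are implemented) for the cis-activation,
  oligomer and compartment variants; their steady states always come from
  the numeric fixed-point solver.
* No bifurcation continuation: multistability, if present in some parameter
  regime, would appear only as initial-condition dependence of
  `steady_state_numeric()`.
* The cis-activation dose–response persists at a substantial fraction of
  its peak at high ligand production when dimers also cis-activate
  (scenario 3), but the precise plateau fraction depends on the swept
  production range and on $k_{ca}$; the tests therefore pin the *contrast*
  with the monomer-only scenario rather than an absolute plateau value.
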