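---
title: "The nucleocytoplasmic actin-shuttling model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The nucleocytoplasmic actin-shuttling model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`nucactin` simulates how a cell can deplete its *nuclear* pool of monomeric
(G-) actin — the gatekeeper of MRTF/SRF transcription — while leaving the
cytoplasmic pool intact, by phosphorylating cofilin in a small signalling
region pinned to the nuclear surface.

The cell is two static circular compartments on a plane: a nucleus of
radius $r_1$ and a surrounding cytoplasmic disc of radius $r_2$ (membership
decided by strict inequalities, so a point exactly on a circle belongs to
neither side of it). Thirteen concentration fields evolve by
reaction–diffusion:

* **Cytoplasm (8 fields):** G-actin $G_c$, F-actin $F_c$, cofilin $C_c$,
  cofilin–actin $\Xi_c$, profilin $P_c$, profilin–actin $\Upsilon_c$,
  phospho-cofilin $\Theta_c$, and a catalytic factor $E_c$ representing the
  nuclear-captured signalling endosomes.
* **Nucleus (5 fields):** $G_n$, $C_n$, $\Xi_n$, $P_n$, $\Upsilon_n$.

All reactions are mass action. In the cytoplasm, G-actin polymerizes at
rate $\gamma_{G_c}(1+\mu_1 E_c)$ and F-actin depolymerizes at
$\gamma_{F_c}$; cofilin and profilin bind G-actin reversibly; cofilin is
phosphorylated at $\alpha_{\Theta_c}(1+\mu_2 E_c)$ and dephosphorylated at
$\gamma_{\Theta_c}$. The nucleus carries only the two reversible binding
reactions — no polymerization, no phosphorylation. The catalytic factor
neither diffuses nor decays ($D_{E_c}=0$, $\gamma_{E_c}=0$), so the two
$\mu$ terms are the only routes by which it acts. (The decay term of its
governing equation is written as a zeroth-order constant; a configuration
switch `ec_decay_order` selects a first-order variant, but both are inert
at $\gamma_{E_c}=0$.)

Membrane fluxes across the nuclear envelope are first-order (Robin)
transfer laws, positive into the nucleus:

* profilin and cofilin exchange **bidirectionally**
  ($\beta_{P_c}P_c-\beta_{P_n}P_n$, analogously for C);
* cofilin–actin crosses **one-way into the nucleus** ($\beta_{\Xi_c}\Xi_c$),
  the importin-mediated carrier of G-actin;
* profilin–actin crosses **one-way into the cytoplasm**
  ($\beta_{\Upsilon_n}\Upsilon_n$), the export carrier;
* G-actin, F-actin, phospho-cofilin and the catalytic factor do not cross.

The outer cell boundary is closed (no flux) for every species. G-actin
itself therefore shuttles *only* as cargo of the two carrier complexes —
this asymmetric carrier architecture is what lets a cofilin-directed
perturbation act selectively on the nuclear pool.

## Parameters, constraints and the sampler

All quantities are in arbitrary model units (concentration, length on a
unit-diameter cell, "time units"); no unit conversions are made anywhere.
The structural constraints the model imposes, enforced by
`validate_parameters()` with a strictness margin of $10^{-9}$, are:

* every coefficient non-negative; $D_{F_c}=D_{E_c}=0$; $\gamma_{E_c}=0$;
* cofilin–actin associates faster, and dissociates slower, in the
  cytoplasm than the nucleus
  ($\alpha_{\Xi_c}>\alpha_{\Xi_n}$, $\gamma_{\Xi_c}<\gamma_{\Xi_n}$):
  the complex forms outside and releases its cargo promptly on arrival;
* the mirror image for profilin–actin, the export carrier;
* symmetric cofilin and profilin transfer
  ($\beta_{C_c}=\beta_{C_n}$, $\beta_{P_c}=\beta_{P_n}$), so the free
  carriers equilibrate to similar levels on both sides;
* import outpacing export ($\beta_{\Xi_c}>\beta_{\Upsilon_n}$), which —
  given fast nuclear dissociation of the import complex — makes the
  baseline nuclear G-actin level exceed the cytoplasmic one;
* nuclear diffusion coefficients strictly above their cytoplasmic
  counterparts, keeping nuclear profiles comparatively flat.

No quantitative kinetic measurements exist for these rates in the system
being modelled, so the shipped default set
(`inst/extdata/default_config.yaml`) is a documented constraint-satisfying
choice made once, designed so that (a) every constraint holds with a wide
margin, (b) the baseline equilibrium is nuclear-enriched (ratio ≈ 4.5),
and (c) the full catalysed model visibly depletes nuclear G-actin within
the standard 400-time-unit horizon. Rates sit in the 0.01–1 per-time-unit
band; cytoplasmic diffusion is $5\times10^{-3}$ (a diffusion length of
order the cell size over the run) and nuclear diffusion tenfold that. The
catalytic region carries $E_{c,\mathrm{init}} = 50$ over a radius
$r_3 = 0.5\,r_1$; together with $\mu_2 = 8$ this makes the region an
essentially absorbing sink for cofilin (local phosphorylation rate ≫ the
diffusive transit rate), so its effect is diffusion-limited and robust to
the time step. A smaller region (e.g. one fifth of the nuclear radius)
is geometrically too weak a sink on this horizon: the capture rate of a
disc in two dimensions scales like $D/\ln(r_2/r_3)$, which is why the
default region is half the nuclear radius. $\mu_1 = 0.08$ keeps the
polymerization pathway a deliberately weaker influence on the nuclear
pool, as only local F-actin conversion — not carrier availability — is
affected by it.

`sample_constrained_parameters()` draws each rate log-uniformly from a
range about a factor of two around its default. Paired,
inequality-constrained rates use disjoint ranges, symmetric transfer
coefficients are drawn once and mirrored, and nuclear diffusion is the
cytoplasmic draw times a ratio in $[5,20]$ — so every draw satisfies the
constraints by construction; a capped rejection loop guards user-supplied
ranges. The sampler emulates parameter *uncertainty around the default
regime*; it does not emulate any measured kinetic data, so passing tests
demonstrate robustness of the qualitative predictions within that regime,
not quantitative agreement with any real cell.

## Discretization and time stepping

The geometry is discretized on a regular cell-centred Cartesian grid
(default $201\times201$; the packaged analyses use 41–101 cells per side,
with every problem size stated where it is used). Compartment membership is decided
by the cell centre, giving a stair-step boundary whose error is $O(h)$;
compartment interfaces are explicit face lists, each face joining exactly
one cell on either side.

Each fixed time step ($\Delta t = 0.01$ time units) applies, in order
(Lie splitting, each sub-step first-order accurate):

1. **Explicit reactions**, cell-local per compartment.
2. **Explicit membrane transfer**: every nuclear face moves
   (flux density × face length × $\Delta t$) of material, evaluated at the
   beginning-of-substep state, removed from the donor cell and added to
   the acceptor cell — exact pairwise conservation by construction. If a
   step would overdraw a donor cell, that face's transfer is clamped to
   empty it exactly and counted; shipped runs report zero such events. A
   documented stability guard warns when
   $\max(\beta)\,\Delta t/h \ge 0.5$.
3. **Implicit diffusion** per species: dimension-split backward-Euler line
   solves (x sweep, then y sweep) on every same-compartment grid segment,
   with reflecting ends. Each tridiagonal system has unit column sums, so
   the solve conserves mass to round-off, is unconditionally stable, and
   preserves positivity; the constant coefficients are prefactored once
   per species, making the per-cell solve division-free.

Numerical hygiene: values in $[-10^{-13}, 0)$ (round-off) are zeroed
silently; values between $-10^{-13}$ and the configurable
`positivity_tolerance` ($10^{-12}$) are zeroed and counted as clip events
(zero in all shipped runs); anything below that, or any non-finite value,
aborts the run naming the species and step. Conserved groups — total
actin $G+F+\Xi+\Upsilon$ across both compartments, total cofilin
$C+\Xi+\Theta$, total profilin $P+\Upsilon$, total catalytic factor — are
recorded in every summary row; over 400 time units they drift at the
$10^{-10}\%$ level.

The splitting error is controlled empirically rather than formally: a
50-step run of the full model agrees with a fully explicit brute-force
integration at $\Delta t/100$ to within 0.5% on every compartment
average; a single cosine eigenmode on a plain rectangle decays within 1%
of the analytic heat-equation rate at 201 grid points; and the headline
depletion fraction changes by under 1% when the step is halved and under
5% when the grid is doubled.

## Equilibration and scenarios

Initial conditions are spatially constant values obtained by relaxing the
catalyst-free model until every compartment average changes by less than
$10^{-6}$ per time unit (relative), then averaging. Because the true
equilibrium profiles are not flat, scenario runs deliberately do not start
at an exact steady state. To shorten the relaxation without changing its
result, the spatial run is seeded from the fixed point of the matching
well-mixed two-compartment ODE (integrated with `deSolve`, using the
discrete compartment areas and perimeter); convergence is judged only on
the spatial run. The starting pools (one unit of total actin split
between free G and F, plus free cofilin and profilin at 0.6) matter only
through the conserved-group totals they imply.

A scenario installs the catalytic field — $E_{c,\mathrm{init}}$ on
cytoplasm cells within $r_3$ of the region centre, zero elsewhere
including nucleus cells inside the ball — and switches the two catalysed
pathways on or off by zeroing $\mu_1$ and/or $\mu_2$ while leaving the
field in place. The depletion metric is
$\Delta = 1 - \bar G_n(t_{\mathrm{end}})/\bar G_n(0)$ on compartment
means; compartment means were chosen because the plotted readout of the
experiments is a compartment-level G-actin level, and means and totals
differ only by the fixed compartment area.

* `knockout_comparison()` runs {both, $\mu_1$-only, $\mu_2$-only,
  neither} from one shared equilibrated state. Under the defaults the
  control stays within 0.5 ppm of its baseline, the $\mu_2$-only run
  reproduces most of the full-model depletion, and the $\mu_1$-only run
  very little — the phosphorylation pathway dominates because it starves
  the *import carrier*, while extra polymerization only converts local
  cytoplasmic G to F.
* `relocation_comparison()` moves the region centre along the ray from
  the nucleus centre, keeping $r_3$ and $E_{c,\mathrm{init}}$ fixed so
  placement is the only manipulated variable; the largest admissible
  distance backs off the outer-tangency supremum by one grid spacing so
  the discretized region stays clear of the outer stair-step boundary.
  Depletion falls monotonically with distance: a remote region still
  phosphorylates cofilin, but no longer shields the import boundary nor
  depletes the carrier where import happens.
* `knockout_robustness()` screens the *ordering* $\Delta(\mu_2\text{-only})
  > \Delta(\mu_1\text{-only})$ across sampled parameter sets. Because
  only the sign of a large separation is at stake, the screen uses a
  200-time-unit horizon (the separation is established well before 100
  time units at the defaults) and a relaxed equilibration
  (tolerance $10^{-5}$, capped at 600 time units); any residual
  equilibration drift enters both arms of a pair identically and cancels
  from the comparison.

Determinism: the integrator itself is deterministic; randomness enters
only through the parameter sampler and the test fixtures, both of which
take explicit seeds and restore the caller's RNG state.

## Known limitations

* The stair-step boundary is first-order accurate; compartment areas and
  the nuclear perimeter carry $O(h)$ error, so absolute levels shift
  slightly with resolution (the depletion fraction moves ~0.1% from 101
  to 201 cells per side).
* All parameter values are surrogates in arbitrary units; the package's
  claims are the *directions and orderings* of the in-silico experiments,
  not quantitative rates in any real cell.
* Transfer is explicit in time, which bounds usable $\beta\Delta t/h$;
  the shipped coefficients sit a factor of ~2.5 below the documented
  guard at the finest default grid.
* The geometry is static and two-dimensional; nuclear deformation,
  three-dimensional effects, discrete pore transport, and any coupling to
  downstream transcription are out of scope.
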