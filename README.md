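# nucactin

Spatial simulation of nucleocytoplasmic actin dynamics: a two-compartment
reaction–diffusion model of how a signalling region captured at the nuclear
surface can selectively deplete *nuclear* monomeric (G-) actin — the signal
that licenses MRTF/SRF-dependent transcription — while cytoplasmic G-actin
is maintained or even rises.

## The model in brief

The cell is two static circular compartments on a plane: a nucleus
(radius r₁) inside a cytoplasmic disc (radius r₂). Thirteen concentration
fields evolve under mass-action kinetics and diffusion — in the cytoplasm
G-actin G꜀, F-actin F꜀, cofilin C꜀, cofilin–actin Ξ꜀, profilin P꜀,
profilin–actin Υ꜀, phospho-cofilin Θ꜀ and a non-diffusing, non-decaying
catalytic factor E꜀; in the nucleus Gₙ, Cₙ, Ξₙ, Pₙ, Υₙ. Key reactions:

- polymerization G꜀ → F꜀ at rate γ_G꜀ (1 + μ₁ E꜀), depolymerization at γ_F꜀;
- reversible cofilin–actin and profilin–actin binding in both compartments;
- cofilin phosphorylation at α_Θ꜀ (1 + μ₂ E꜀), dephosphorylation at γ_Θ꜀.

Across the nuclear envelope, profilin and cofilin exchange bidirectionally
(first-order Robin fluxes), cofilin–actin is imported one-way into the
nucleus, profilin–actin exported one-way into the cytoplasm; G-actin only
crosses as cargo of these carriers. The outer boundary is closed. The
system is integrated with a conservative semi-implicit finite-volume
scheme on a regular Cartesian grid (explicit reactions and transfers,
implicit dimension-split diffusion; fixed time step 0.01 time units),
with conserved-group drift at the 10⁻¹⁰ % level over 400 time units.

The two in-silico experiments this package reproduces:

1. **Knockouts** — switching off catalysed cofilin phosphorylation
   (E꜀μ₂ = 0) largely abolishes nuclear G-actin depletion, whereas
   switching off catalysed polymerization (E꜀μ₁ = 0) barely affects it:
   the phosphorylation pathway starves the import carrier.
2. **Relocation** — moving the catalytic region away from the nuclear
   surface (same size and strength) reduces the G-actin mobilized from
   the nucleus, rationalizing why the signalling ensemble is captured at
   the nuclear envelope.

## Worked example

```r
library(nucactin)

base <- scenario_spec(grid = 61, t_end = 150, snapshot_times = c(0, 50, 150))
eq <- equilibrate(base$params, base$geom, base$cfg, nx = 61)
glance(eq)
#> # A tibble: 1 × 6
#>   mean_Gn mean_Gc gn_gc_ratio converged    residual t_relaxed
#>     <dbl>   <dbl>       <dbl> <lgl>           <dbl>     <dbl>
#> 1   0.581   0.128        4.54 TRUE      0.000000863       245

ko <- knockout_comparison(base, equilibrium = eq)
tidy(ko)
#> # A tibble: 4 × 4
#>   scenario mu1_active mu2_active  depletion
#>   <chr>    <lgl>      <lgl>           <dbl>
#> 1 both     TRUE       TRUE       0.352
#> 2 mu1_only TRUE       FALSE      0.0481
#> 3 mu2_only FALSE      TRUE       0.308
#> 4 neither  FALSE      FALSE      0.00000301
```

Reading the numbers: at the catalyst-free baseline the nuclear G-actin
mean exceeds the cytoplasmic mean ~4.5-fold. Over 150 time units the full
model (`both`) depletes the nuclear mean by 35%; with only the
phosphorylation pathway active (`mu2_only`) depletion is nearly as large
(31%), with only the polymerization pathway (`mu1_only`) it collapses to
5%, and the control (`neither`) stays at its baseline — the ordering that
identifies cofilin phosphorylation as the dominant route. `autoplot(ko)`,
`autoplot(run_scenario(base))` and `plot_snapshot()` (viridis G-actin
stills) visualize these results; `relocation_comparison(base)` runs the
region-relocation experiment.

A command-line driver wrapping the same functions lives at
`inst/cli/nucactin.R`
(`equilibrate | run | knockouts | relocate`, with `--config`, `--out`,
`--seed`, `--grid`, `--t-end`); configurations are YAML
(see `inst/extdata/default_config.yaml`), summaries CSV, snapshots a
self-describing JSON grid container, and every output directory carries a
JSON manifest sufficient to re-execute the run.

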