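# pmfbind

Umbrella sampling → WHAM → binding free energy, plus the standard
patch-clamp curve fits, for studying state-dependent drug block of ion
channels.

## The problem

High-affinity blockers of the cardiac hERG (Kv11.1) potassium channel —
dofetilide being the canonical example — bind inside the pore cavity, and
their affinity depends both on the channel's conformational state (open
vs. open-inactivated) and on the drug's ionization state: an ionizable
basic amine means a pH-dependent mix of neutral and cationic drug.
Molecular simulation probes this with umbrella sampling along the pore
axis: a ladder of harmonically restrained windows along the
reaction coordinate z (ligand centre of mass relative to the
selectivity-filter anchor), combined into a potential of mean force
(PMF) w(z), and finally converted into an effective dissociation
constant.

`pmfbind` implements that inference chain as reusable, tested R code:

1. **`synthetic_data`** — analytic ground-truth potentials and exact
   biased-Boltzmann window trajectories (plus noisy Hill, exponential and
   Boltzmann measurement curves), so the whole chain can be validated
   without any MD engine;
2. **`wham_core`** — histogramming with burn-in, the self-consistent
   weighted histogram analysis method (WHAM) with Anderson acceleration,
   bulk anchoring, and bootstrap uncertainties driven by integrated
   autocorrelation times;
3. **`binding_thermo`** — the PMF → K_D → ΔG conversion under a
   flat-bottom cylindrical restraint, state comparisons, error
   propagation, and Henderson–Hasselbalch ionization;
4. **`ephys_fits`** — Hill concentration–response, single-exponential
   use-dependent block, and Boltzmann g–V fits with Welch comparisons
   across conditions;
5. **`io_cli`** — file formats (umbrella metadata + trajectory dialect of
   the common 1-D WHAM tools, PMF TSV, reports), flat key=value configs,
   and a `pmfbind` shell command (`exec/pmfbind`) with subcommands
   `simulate`, `wham`, `bind`, `fit`, `pipeline`.

## The core quantities

With w(z) offset to zero in bulk, the effective dissociation constant
under a lateral flat-bottom cylindrical restraint of radius R is

    K_D = [ π R² N_A · 10⁻²⁷ · ∫_site exp(−w(z)/k_B T) dz ]⁻¹

(z in Å, w in kcal/mol, K_D in mol/L), and the standard binding free
energy is

    ΔG = k_B T ln (K_D / c⁰),   c⁰ = 1 M.

Defaults are T = 310.15 K, R = 10 Å, windows every 0.5 Å with
k = 10 kcal mol⁻¹ Å⁻², WHAM tolerance 10⁻⁷ kcal/mol, and a burn-in of
2/22 of each window.

## Worked example

A synthetic "inactivated-like" system (one deep −18 kcal/mol well) at the
standard 60-window layout, reconstructed and converted to a binding
constant:

```r
library(pmfbind)
pot    <- preset_potential("inactivated-like")
layout <- make_window_layout(-38, -8.5, spacing = 0.5, k = 10)
series <- simulate_windows(pot, layout, sampler_params(n_steps = 20000),
                           seed = 42)
hists  <- build_histograms(series, bin_width = 0.1, burn_in_fraction = 2/22)
sol    <- solve_wham(hists, tolerance = 1e-7)
sol
#> WHAM solution: 60 windows, 305 bins (305 supported)
#>   converged after 627 sweeps, final residual 9.68e-08 kcal/mol (tol 1e-07)

pmf <- offset_to_bulk(pmf_from_solution(sol), bulk_range = c(-38, -33))
pmf
#> PMF profile: 305 bins (305 supported) on [-38.85, -8.45] Angstrom
#>   offset: bulk-zero; T = 310.15 K; bulk [-38.00, -33.00]
#>   min w = -17.941 kcal/mol at z = -9.95

binding_result(pmf, thermo_params(), label = "synthetic inactivated-like")
#> Binding result [synthetic inactivated-like]
#>   K_D     = 1.46 pM
#>   Delta G = -16.80 kcal/mol
#>   site    = [-19.15, -8.45] Angstrom
#>   effective 1-D estimate under a cylindrical restraint of R = 10 Angstrom
```

The reconstructed well depth (−17.94 kcal/mol) recovers the ground truth
(−18) to within the sampling noise of 2×10⁴ samples per window, and the
picomolar K_D illustrates how a deep cavity well translates into lock-in
binding. Smaller building blocks work standalone:

```r
format_kd(6.7e-8)
#> [1] "67 nM"
delta_delta_g(binding_result(kd = 1.32e-9), binding_result(kd = 6.7e-8))$ddg
#> [1] -2.420371
100 * protonated_fraction(7.4, 7.0)   # cationic percentage at pH 7.4
#> [1] 28.47472
```

The same chain runs from a shell:

```sh
pmfbind pipeline --config inst/extdata/example_run.cfg --seed 1 --out out/
```

## Scope

The package covers the analysis layer only: no molecular mechanics,
docking, or raw-trace processing. PMFs enter as window time series (or
synthetic equivalents); electrophysiology enters as reduced tidy tables.
All reported K_D values are effective, estimated from a one-dimensional
approximation for the binding process under the cylindrical restraint.
See `vignettes/pmf-binding-workflow.Rmd` for the methods account.
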