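# rasconf

Conformational-state analysis of GTP-bound Ras from molecular-dynamics
trajectories.

GTP-bound Ras interconverts between an "inactive" **state 1**, in which the
Thr35–Mg²⁺ hydrogen bond is broken and switch I moves off the nucleotide,
and an "active" **state 2** with that bond intact. Within state 2 the
Tyr32 side-chain orientation defines three substates: **2OX** (Tyr32 into
the GTP pocket; OH32–Oγ ≈ 2.7 Å), **2OY** (Tyr32 parallel to the pocket,
toward Ala18; OH32–O18 ≈ 4.3 Å, OH32–Oγ ≈ 11.3 Å) and **2OZ** (Tyr32
toward bulk solvent, the GAP-binding-compatible orientation;
OH32–Oγ ≈ 7.5 Å). `rasconf` assigns every trajectory frame to
{S1, S2_OX, S2_OY, S2_OZ, UNASSIGNED} by a decision cascade on five
characteristic distances,

```
S1     if  d(OG35, Mg)  > t_mg        (default 2.6 Å)
S2_OX  if  d(OH32, Oγ)  ≤ t_ox        (default 4.5 Å)
S2_OY  if  d(OH32, O18) ≤ t_oy        (default 6.5 Å)
S2_OZ  if  d(OH32, Oγ)  ≤ t_oz_max    (default 10.0 Å)
UNASSIGNED otherwise
```

followed by a mode-filter debounce, and computes the ensemble statistics
used to characterise the states: pooled occupancies with dwell and
transition structure, per-residue Cα RMSF per (sub)state (core-fitted
Kabsch superposition, RMSF_i = √⟨|r_i − ⟨r_i⟩|²⟩), essential-dynamics PCA
(3N×3N Cα covariance, leading eigenvectors and per-residue mode
mobilities), dynamic cross-correlation matrices
C_ij = ⟨Δr_i·Δr_j⟩ / √(⟨|Δr_i|²⟩⟨|Δr_j|²⟩), Na⁺ counts within 4.5 Å of
GTP per (sub)state, and two membrane reaction coordinates (β1-sheet tilt
against the membrane normal; E132–L184 Cα distance). A fully seeded
synthetic-trajectory generator emulates all of these observables so the
entire pipeline is testable without MD data. The intended users are
simulators of Ras (or other switch-containing GTPases) who want a
reproducible, scriptable state assignment instead of ad hoc plotting.

Structures are read from PDB; trajectories from DCD or multi-model PDB
(`coord_unit = "nm"` rescales nm-unit input). Everything user-facing is a
tibble and pipes cleanly; results have `autoplot()` methods and the PCA
fit has broom-style `tidy()`/`glance()`.

## Worked example

```r
library(rasconf)

dir <- tempfile()
paths <- synthesize_scenario("membrane_WT", dir, n_frames = 5000,
                             tau = 50, seed = 42)
st <- read_structure(paths$structure)
tr <- read_trajectory(paths$trajectory, st)
an <- run_analysis(st, tr)

an$occupancy
#> # A tibble: 5 × 4
#>   label      n_frames fraction mean_dwell
#>   <chr>         <int>    <dbl>      <dbl>
#> 1 S1             1584    0.317       75.4
#> 2 S2_OX          3091    0.618      129.
#> 3 S2_OY           325    0.065       46.4
#> 4 S2_OZ             0    0           NA
#> 5 UNASSIGNED        0    0           NA

an$ion_summary
#> # A tibble: 3 × 4
#>   label mean_ions sd_ions n_frames
#>   <chr>     <dbl>   <dbl>    <int>
#> 1 S1        1.69    1.31      1584
#> 2 S2_OX     0.432   0.667     3091
#> 3 S2_OY     0.729   0.856      325
```

The occupancy table says this 5000-frame membrane-bound wild-type run
spends ~62% of its frames in the dominant 2OX substate and ~32% in state 1
(on a single trajectory this short, the Markov dwell structure leaves
sampling error of several percentage points around the scenario's
stationary values of 53%/39%). The ion summary shows the open state-1
pocket admitting ~1.7 Na⁺ on average against ~0.4 when Tyr32 blocks the
pocket in 2OX — the per-frame counts are drawn per state from the
scenario's Poisson intensities (1.72/0.42/0.75/0.06). `an$rmsf`,
`an$pca`, `an$dccm` and `an$rc_hist` hold the per-state profiles;
`autoplot()` works on each result, and `write_analysis(an, dir)` writes
the CSV/JSON/matrix outputs plus a checksummed manifest.

A thin command-line wrapper with `synthesize` / `analyze` / `compare`
subcommands lives at `inst/scripts/rasconf-cli.R`.

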