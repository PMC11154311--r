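---
title: "Classifying GTP-bound Ras conformational (sub)states from MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying GTP-bound Ras conformational (sub)states from MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rasconf)
```

## The scientific problem

GTP-bound Ras proteins interconvert between two main conformational states:
an "inactive" state 1, in which the hydrogen bond between the Thr35
side-chain hydroxyl and the catalytic Mg²⁺ ion is broken and switch I pulls
away from the nucleotide, and an "active" state 2 with that bond intact.
Within state 2 the orientation of the Tyr32 side chain further splits the
ensemble into three substates:

* **2OX** — Tyr32 points into the GTP-binding pocket (toward residue 12);
  its ring hydroxyl (OH32) sits in hydrogen-bonding distance of the GTP
  γ-phosphate oxygen (Oγ), around 2.7 Å.
* **2OY** — Tyr32 lies parallel to the pocket, toward Ala18; OH32 makes a
  close ~4.3 Å contact with the Ala18 backbone oxygen while sitting
  farthest (~11.3 Å) from Oγ.
* **2OZ** — Tyr32 faces bulk solvent, the orientation compatible with GAP
  binding and its arginine finger; OH32–Oγ fluctuates broadly around
  7.5 Å.

These geometric signatures make the state assignment a per-frame
classification problem on a handful of inter-atomic distances, which is
what `rasconf` implements, together with the ensemble statistics used to
characterise the states (occupancies, dwell/transition structure,
per-residue RMSF, essential-dynamics PCA, dynamic cross-correlation
matrices), Na⁺ accessibility of the GTP pocket, and two membrane reaction
coordinates (the β1-sheet tilt against the membrane normal and the
E132–L184 Cα distance measuring HVR stretch).

## The classifier

Five distances are extracted per frame (names follow the field's atom
labels; subscripts are residue numbers): O12–Oγ, OH32–O18, OG35–Mg,
OH32–Oγ, OH32–OH40. Labels come from a fixed decision cascade:

1. **S1** if d(OG35, Mg) > `t_mg` (the Thr35–Mg²⁺ bond counts as broken);
2. else **S2_OX** if d(OH32, Oγ) ≤ `t_ox`;
3. else **S2_OY** if d(OH32, O18) ≤ `t_oy`;
4. else **S2_OZ** if d(OH32, Oγ) ≤ `t_oz_max`;
5. else **UNASSIGNED**.

The cascade order puts the sharpest signatures first (the short OX and OY
contacts), leaving OZ as the residual bulk-facing orientation, and never
silently merges unassignable frames.

### Thresholds (defaults, all configurable)

| parameter | default | units | rationale |
|---|---|---|---|
| `t_mg` | 2.6 | Å | intact bond sits near 2.0 Å; broken-bond trajectories jump far above 3 Å, so 2.6 Å adds a thermal margin |
| `t_ox` | 4.5 | Å | between the 2.7 Å OX center and the 7.5 Å OZ center |
| `t_oy` | 6.5 | Å | between the 4.3 Å OY contact and the >12 Å of other substates |
| `t_oz_max` | 10.0 | Å | above the broad 7.5 Å OZ center, below the 11.3 Å OH32–Oγ value typical of OY |
| `smoothing_window` | 5 | frames | dwell segments, not per-frame flicker, carry the state signal |

The published distances are *centers* of state distributions, not cutoffs;
the thresholds here are this package's own construction (midpoints between
adjacent centers) and should be revisited for force fields or systems with
different geometry.

Raw labels are debounced with a centered mode filter (window 5 frames,
ties broken toward the previous smoothed label). Occupancies pool
trajectories weighted by frame count, mirroring distributions computed
over all performed simulations of a condition.

## Ensemble statistics

All structural statistics run on the Cα trace (G-domain residues 1–165).
The default superposition fit set is the **core**: all trace residues
except switch I (30–40) and switch II (58–76). The switches move by
several Å between states while the core stays within ~1 Å of the crystal
structure, so fitting on the core prevents switch motion from leaking into
core fluctuations; `fit_residues` accepts any residue set. Superposition
is a least-squares Kabsch/SVD fit; per-state RMSF and PCA use a two-pass
mean structure (fit to the first frame, average, refit to the mean —
`iterate_mean = TRUE` iterates to a fixed point). The DCCM is the
normalized covariance of per-residue displacement vectors; residues with
exactly zero variance get zeroed rows with a warning rather than NaNs.
PCA mode mobilities are reported as `sqrt(eigenvalue) * |residue
3-vector|`, in Å, so the per-residue profiles of the leading modes are on
a physical scale.

Ion accessibility follows a contact-shell criterion: a Na⁺ ion counts when
its minimum distance to *any* GTP atom is within 4.5 Å (configurable;
minimum-image correction applies whenever a periodic box is present). The
per-state summary reports the population SD (divisor *n*), a descriptive
spread of the per-frame counts.

### Numerical choices

* Distances use the minimum-image convention when a box is supplied and
  plain Euclidean distances otherwise. Intra-protein distances are far
  below half-box in any realistic setup, so this cannot change classifier
  output, but correctness for ions requires it.
* The β1-sheet direction is the first principal axis of the four Cα
  positions of residues 2–5, oriented from residue 2 toward residue 5.
  This is robust to local bends and reduces to the simple Cα(2)→Cα(5)
  vector for collinear points. The membrane normal defaults to the
  laboratory +z axis (bilayers are conventionally built in the xy plane)
  and is configurable for tilted boxes. Angles are reported in [0, 180]°.
* Superposition requires at least 3 non-collinear fit points and errors
  otherwise; eigenvalues are clamped at zero against roundoff; DCCM
  entries are clamped to [−1, 1].

## The synthetic trajectory generator

No trajectories are deposited for the source systems, so the generator
stands in for them: it emulates exactly the observables the pipeline
consumes, not protein physics. Each scenario preset
(`solution_WT`, `solution_G12V`, `membrane_WT`, `membrane_G12V`)
parameterizes:

* **State sequence** — a Markov chain that stays put with probability
  `1 − 1/tau` and otherwise redraws the state from the stationary
  distribution π (current state included). Drawing from π itself — rather
  than from π restricted to the *other* states — is what makes π the exact
  stationary distribution (the restricted variant converges to
  π(1−π)/Z instead); the price is a mean dwell of `tau/(1−π_i)` frames
  rather than `tau`. Default `tau` = 50 frames, a dwell scale consistent
  with trajectories that show long state segments with sharp transitions.
* **Distance geometry** — role atoms are placed by direct construction:
  Mg at the cluster origin, Oγ at a fixed 2.0 Å coordination offset, OG35
  along +x at its sampled Mg distance, and OH32/O18/O12/OH40 by spherical
  sampling at distances drawn from per-state Gaussians. The OH32 direction
  is rejection-sampled so that OH32 always remains closest to the *same*
  γ-oxygen (O1G), keeping the γ-oxygen role binding stable across frames.
  An optional joint Oγ–O18 target turns the O18 placement into a
  two-sphere intersection; infeasible combinations raise a
  triangle-inequality error.
* **Cα trace** — a fixed smooth template curve of 165 residues (plus an
  HVR tail to 186 for membrane scenarios) with Gaussian jitter; switch
  residues get state-dependent noise scales so state 1 shows the largest
  switch-I fluctuations and OZ the smallest, matching the qualitative RMSF
  ordering of the source systems. For membrane scenarios each frame is
  rotated to a sampled β1 tilt angle and L184 is re-placed at a sampled
  E132 distance.
* **Ions** — per frame, `k ~ Poisson(λ_state)` ions are placed inside the
  4.5 Å shell of a random GTP atom and the remaining Na⁺ atoms (10 decoys
  plus unused shell slots, 22 total — trajectory formats need a constant
  atom count) beyond 8 Å. `k` is truncated at 12 shell slots; the
  truncated mass is below 10⁻⁶ at the largest preset λ of 2.53.

Randomness is split into three seeded substreams (states, geometry, ions),
so enabling or disabling ions never perturbs the state sequence — and
generation is fully deterministic: identical seeds give byte-identical
files.

### Preset parameter provenance

The stationary occupancies, the per-state distance centers and the
per-state ion Poisson means are taken from the published characterization
of the four conditions. Three classes of choices are this package's own
calibration, recorded here because the source does not state them:

* **Distance SDs** (no spreads are published): 0.4 Å default, with 0.15 Å
  for the tight OG35–Mg coordination in state 2, 1.0 Å for the broad
  OH32–Oγ distribution of OZ, 1.5 Å/2.5 Å for the wide state-1 OG35–Mg
  and OH32–Oγ distributions, and 1.0 Å for the "greater than 12 Å"
  OH32–O18 distances.
* **Occupancy residuals.** The published "~" percentages of a condition do
  not sum to 100. Where they fall short (solution WT: 93%; solution G12V:
  95%; membrane G12V: 80%), the shortfall is emitted as an explicit
  UNASSIGNED-margin state — frames whose Tyr32 orientation sits outside
  all three substate signatures (OH32–Oγ ≈ 12.5 Å with no Ala18 contact,
  Thr35 bond intact) — rather than being silently added to the largest
  state, so each printed percentage is the *expected labeled fraction* of
  its state. Where they overshoot (membrane WT: 103%), the four states are
  scaled proportionally. The margin state also keeps the classifier's
  UNASSIGNED accounting honest in end-to-end tests.
* **Reaction-coordinate distributions** (published only as contour
  plots): per-state angle/distance means and SDs chosen to reproduce the
  qualitative picture — a specific, compact-HVR state 1 in WT that becomes
  broad under G12V, an OX substate that turns membrane-parallel
  (angle ≈ 90°) with a medium-stretched HVR in the mutant, and overlapping
  OY/OZ at intermediate tilt. Solution-only scenarios have no HVR; their
  `rc_dist` is absent by construction.
* The solution-WT OX occupancy is quoted both as ~30% and as ~25% in
  different parts of the source; the presets use 30%, the value attached
  to the occupancy distribution itself.
* G12V presets set π(2OZ) = 0 exactly (the GAP-binding substate is never
  sampled by the mutant) and move the residue-12 backbone-O–Oγ center
  from 5.3 Å to 8.5 Å (the bulkier Val12 pushes this distance above 8 Å).
* The ion λ of the margin state (0.5) is a neutral intermediate value;
  margin frames are reported under UNASSIGNED and never enter per-state
  comparisons.

### What passing tests do and do not show

The generator reproduces the *signatures* the method reads — distance
distributions, dwell structure, switch-noise ordering, shell counts — not
molecular mechanics. Recovery tests therefore validate the pipeline's
correctness (geometry, classification logic, estimators, I/O) and its
statistical calibration, but they cannot validate the thresholds against
real force-field output, PBC wrapping artifacts, or correlated
multi-distance fluctuations of a physical switch region: on real
trajectories the distance distributions need not be Gaussian or
independent, and UNASSIGNED fractions may behave differently.

## Problem sizes and statistical bands

Synthetic-recovery tests use a single 20000-frame trajectory per condition
with `tau` = 50 — an effective sample size of about
`n / (2·tau − 1) ≈ 202` independent draws — and accept occupancies within
3 standard errors of the generator's stationary values; distance and ion
means are tested at 3 SE with 5000 pure-state frames and ~2000-frame
Poisson summaries. The acceptance script pools five such trajectories per
condition (frame-weighted, as the occupancy estimator is defined), since
the reference distributions are themselves pooled over all simulations of
a condition; pooling shrinks the chain-autocorrelation SE from ~4–5 to
~2 percentage points on the major states. Unit-level operators are tested
against closed forms and brute-force oracles at much tighter tolerances
(superposition 10⁻⁹ Å, RMSF closed form 10⁻⁸ Å, DCCM constructions
10⁻¹⁰, PCA trace identity 10⁻⁶ relative).

## Worked example

```{r example, eval = FALSE}
library(rasconf)

dir <- tempfile()
paths <- synthesize_scenario("membrane_WT", dir, n_frames = 5000,
                             tau = 50, seed = 42)
st <- read_structure(paths$structure)
tr <- read_trajectory(paths$trajectory, st)

an <- run_analysis(st, tr)
an$occupancy
an$ion_summary
tidy(an$pca[["S1"]])

library(ggplot2)
autoplot(an$occupancy)
autoplot(an$rmsf)
plot_rc_histogram(an)
```

## Known limitations

* Trajectory input is DCD or multi-model PDB; compressed GROMACS formats
  are not read (convert externally, or pass `coord_unit = "nm"` for
  nm-unit DCDs).
* Only orthorhombic boxes are handled by the minimum-image correction.
* The classifier is geometric and threshold-based by design; it does not
  learn cutoffs, estimate kinetics, or build Markov state models.
* The synthetic Cα trace is a template curve, not a folded protein;
  RMSD magnitudes relative to a crystal reference are not meaningful on
  synthetic data, only their orderings.
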