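---
title: "Whole-lung dust dosimetry and the airway obstruction ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-lung dust dosimetry and the airway obstruction ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respdose)
```

## The problem

Acute inhalation limit tests expose rats for 4 h to very high concentrations
of poorly soluble dusts (up to 5 mg/L under GHS rules). At such
concentrations, enough material can deposit in individual airways to
physically obstruct them — a rat-specific physical effect rather than a
chemical toxicity, and one that matters for whether such findings should be
extrapolated to humans. `respdose` implements the computational side of that
question: a whole-lung deposition model for lognormal inert aerosols in
rat-like and human airway trees, and, on top of the per-airway deposited
masses, an *obstruction ratio* statistic

$$ r_j = \frac{(6 V_j / \pi)^{1/3}}{d_j}, \qquad V_j = \frac{m_j}{\rho}, $$

the diameter of a sphere containing the total particle volume deposited in
airway $j$ over the exposure, divided by that airway's diameter $d_j$. A
ratio of 1 means the coalesced deposit is as wide as its airway; ratios above
0.5 flag vulnerability to significant obstruction.

## Aerosol model

An exposure atmosphere is a lognormal mass distribution specified by its MMAD
(µm), GSD, particle density ρ (g/cm³) and mass concentration C (mg/m³). The
engine integrates over the distribution by discretizing it into geometrically
spaced aerodynamic-diameter bins covering MMAD·GSD^±4 (1000 bins by default),
with lognormal mass weights renormalized to 1. Refining from 1000 to 10,000
bins changes regional deposition totals by well under 0.1 percentage point,
which is why 1000 is the default; a GSD of 1 collapses to a single
monodisperse bin.

Particle transport properties are evaluated in CGS units at body conditions
(T = 310 K, µ = 1.89·10⁻⁴ g cm⁻¹ s⁻¹, λ = 0.0712 µm, g = 981 cm s⁻²; all
recorded in `constants.yaml` and echoed into every results file):

* Cunningham slip correction `C(d) = 1 + (λ/d)(2.514 + 0.8 e^(−0.55 d/λ))`;
* settling velocity `v_ts = ρ₀ d_ae² g C(d_ae) / (18 µ)` under the
  aerodynamic-diameter convention (ρ₀ = 1 g/cm³);
* Stokes–Einstein diffusivity `D = k_B T C(d) / (3 π µ d)`.

### Inhalability

Not all airborne mass enters the respiratory tract. For humans, inhalability
is unity for the micron-sized aerosols considered here (it only declines
above ~10 µm). For rats, inhalability declines already above ~1 µm; the
package uses a logistic curve in log diameter,
`IF(d) = 1 − 1/(1 + exp(a − b log d))`, which tends to 1 for fine particles
and decreases monotonically with size. Because published inhalability data
constrain the outcome better than the coefficients, `a` and `b` were fixed
once so that the two study aerosols (MMAD 2.74 µm / GSD 2.8 and 2.01 µm /
GSD 3.0) attain mass-weighted inhalable fractions of 0.745 and 0.775 — inside
the 74–78% band reported for rats — and are frozen in `constants.yaml`.
`calibrate_inhalability()` reproduces them.

```{r inhalability}
inhalable_fraction(aerosol_spec(2.74, 2.8), "rat")
inhalable_fraction(aerosol_spec(2.74, 2.8), "human")
```

## Airway geometry

An `airway_tree` is a rooted tree of conducting (TB) and pulmonary (PUL)
airway segments with per-airway length, diameter, branching angle (from the
parent axis), gravity angle (from the gravity vector, upright posture),
multiplicity and distal volume. Two geometries ship with the package:

* **Human**: the symmetric typical-path whole-lung model after Yeh & Schum
  (1980) — 17 tracheobronchial generations (trachea = generation 1) plus 7
  pulmonary generations, 2^(g−1) identical airways per generation,
  16,777,215 airways in total. It is stored per generation; per-airway
  quantities are per-single-airway values, so nothing ever materializes 16.7
  million records. The morphometry table is used at its published inflation.
* **Rat**: no cast-based rat geometry is published with the study design, so
  the package generates a clearly labelled *synthetic monopodial surrogate*:
  28 conducting generations with a persistent axial trunk, minor daughters
  branching at steep angles, pulmonary outgrowths only from conducting
  generations 8–28, and 8 pulmonary generations appended to every terminal
  bronchiole (36 generations deep in total). Diameter and length ratios are
  lognormal draws truncated below 1, one seeded RNG stream per tree, so a
  given seed yields a byte-identical geometry CSV. Defaults produce a few
  thousand conducting airways — the right order of magnitude for desk-scale
  heterogeneity — with no claim of fidelity to any particular lung cast.

Distal volumes combine airway lumina with alveolar volume. Alveolar volume
(human default 3910 cm³, consistent with the near-total-capacity inflation of
the embedded table; rat default 4 cm³) is apportioned **equally across the
alveolated generations**, then equally among each generation's airways. This
choice is load-bearing: it places enough expanding volume in the respiratory
bronchioles that the tidal front (below) dies out inside generation 21,
reproducing the known behavior that the terminal alveolar generations 22–24
— 87.5% of all airways — receive no deposition during resting breathing.
Apportioning alveolar volume per *airway* instead (weighting the last
generations far more) pushes fresh aerosol into generation 22 and was
rejected for that reason.

## The deposition engine

`run_deposition()` performs serial filtration over one tidal breath per size
bin and aggregates by mass weight; deposited mass then scales linearly with
concentration, breathing frequency and the 4-h duration (no clearance acts on
this acute time scale, and deposition never alters the airflow — the model is
one-way coupled, so material keeps penetrating as if no upstream obstruction
existed).

1. **Inhalability** (rat only) scales the mass entering the nose.
2. **Head filtration.** The extrathoracic region is modeled empirically as
   `η_ET = 1 − exp(−a (d_ae² Q)^b)` per species/route, with Q the mean
   inspiratory flow. The `a` coefficients are calibrated once against the
   reference human head fractions (51.3% nasal, 14.3% oral of inhaled mass
   for the 2.74 µm / GSD 2.8 aerosol at 625 mL, 12 breaths/min) and the rat
   nose-only head fraction (34.5% of inhalable mass at resting rat
   ventilation); `calibrate_extrathoracic()` reproduces them. The exponent b
   sets the *shape*: b = 0.5 for the nasal route (nasal collection saturates
   shallowly over the impaction parameter), b = 1 for the sharper,
   impaction-dominated oral and rat nose-only routes.
3. **Tidal front.** Root flow is V_T/(inspiratory fraction × breath period),
   split at each branch in proportion to distal volume. The tidal air is
   apportioned over the alveolar (expanding) volumes; air bound for an airway
   must first displace the particle-free dead-space gas of the airways ahead
   of it (extrathoracic volume plus proximal lumina, charged per path).
   Airways beyond the front receive no aerosol at all. Residual lung gas is
   assumed particle-free, which slightly underestimates re-breathed aerosol.
4. **Inspiratory transit.** Each airway filters the through-flowing aerosol
   with combined efficiency `η = 1 − (1−η_I)(1−η_S)(1−η_D)`: arccos-form
   impaction in the turning parameter θ·Stk, exponential gravitational
   sedimentation `1 − exp(−(4/π) v_ts L sin γ / (d U))`, and an Ingham-type
   series for diffusion in `x = D L/(4 U R²)`.
5. **Parked-air residence.** Air that stops in an airway (its lumen or its
   own alveoli) deposits by sedimentation and diffusion over its residence
   time. Parcels stack last-in-first-out: air parked proximally entered the
   mouth last and leaves first; the deepest air sits for nearly the whole
   breath. Each airway gets a residence window from the same dead-space
   bookkeeping as the front, minus the round-trip transit time already
   charged as transit deposition, and the exponential survival is averaged
   exactly over the window. Alveolus-stored air settles over the alveolus
   scale (280 µm human, 80 µm rat) rather than the duct diameter,
   volume-weighted against lumen-stored air. An end-inspiratory pause
   (`pause_fraction`, default 0 in the square-wave cycle with inspiratory
   fraction 0.5) extends every window.
6. **Expiratory transit.** The surviving air exits leaves-to-root through the
   same efficiencies at the expiratory flow (angles unchanged).

Mass is conserved identically: head + TB + PUL + exhaled = 1 for every bin,
and the engine refuses to return if the balance drifts beyond 10⁻⁹. The
whole computation is vectorized per size-bin chunk; the human per-generation
tree runs in tens of milliseconds and a ~20,000-airway rat surrogate in
about 20 s at 1000 bins.

```{r human}
nasal <- run_deposition(
  exposure_scenario(aerosol_spec(2.74, 2.8, 1, 5212),
                    ventilation_pattern(625, 12, "nasal"),
                    builtin_human_tree(), inhalability_on = FALSE))
nasal$regional
```

## Obstruction analysis

Per-airway deposited masses (per single airway, so symmetric and expanded
representations agree exactly) are converted to coalesced-sphere diameters at
the particle density and divided by the airway diameters; the head region is
excluded. Because fractions are concentration-invariant, ratios scale as
(C·t)^(1/3) — the package's tests verify this exactly. Ratios are binned into
half-open intervals (right-open, last bin unbounded): quartile edges
0/0.25/0.5/0.75/1 for rat reporting and 0/0.1/0.2/0.3/0.4/0.5 for human
reporting, counted with multiplicities, for TB and PUL separately and
combined. `compare_profiles()` places profiles side by side and flags whether
counts above each edge grow monotonically across, e.g., increasing exposure
concentration. Ratios are computed from mass at the scenario's particle
density (unit density in the study design, where mass and volume coincide);
no packing-porosity correction is applied, and the density is exposed as a
parameter for sensitivity analyses.

## What the synthetic rat surrogate does and does not show

The surrogate reproduces the *structural* features the analysis relies on —
monopodial asymmetry, early pulmonary outgrowths, realistic airway counts and
diameters spanning the termination scale — and therefore supports the
property-level conclusions: strict growth of obstructed-airway counts with
concentration, the downward shift of high-ratio mass at lower concentrations,
and the species contrast against the human tree (no human airway exceeds
ratio 0.5 under the same exposure, while a large share of surrogate rat
airways do). Quantities tied to the unpublished cast geometry — exact airway
counts per ratio band, per-lobe spreads, extreme ratios of specific airways —
are *not* reproducible from a surrogate and are not asserted anywhere in the
package or its tests.

## Numerical choices and degenerate inputs

* Discretization: 1000 bins over ±4 ln GSD; convergence tested at 100/1000/
  10,000.
* Efficiencies are clamped to [0, 1]; the impaction arccos form caps at
  θ·Stk = 1; residence survival switches to a midpoint evaluation when
  k·Δt < 10⁻¹⁰ to avoid 0/0.
* Monodisperse aerosols (GSD = 1) bypass discretization.
* Zero concentration yields zero masses with unchanged fractions; zero mass
  yields obstruction ratio 0.
* Trees are validated before every run; violations (orphans, non-positive
  dimensions, generation gaps, cycles) are reported as data by
  `validate_tree()` and refused by the engine.
* All randomness lives in the tree generator, behind a single integer seed;
  the physics is fully deterministic, so pipeline reruns are byte-identical.

## Known limitations

The engine is a typical-path/serial-filtration model, not CFD: it cannot
localize deposits within an airway (hot spots at bifurcations), does not
couple deposits back onto the airflow, and treats the head as a single
empirical filter. Mucociliary and macrophage clearance are deliberately
disabled — over a 4-h acute exposure the deposited dose is the relevant
metric — so the package must not be used unmodified for repeated-dose
retention questions. The residence-time treatment averages over parcels
within an airway and ignores axial mixing between tidal air and reserve air.
Calibrated coefficients (head filtration, rat inhalability) are anchored to
resting ventilation and micron-scale dust aerosols; extrapolation to exercise
breathing or nanoparticle number-based metrics would need recalibration.
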