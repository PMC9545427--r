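---
title: "Modelling hyperoxia-induced R1 changes in tissue voxels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hyperoxia-induced R1 changes in tissue voxels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Oxygen-enhanced MRI (OE-MRI) infers tissue oxygenation from the change in the
longitudinal relaxation rate R1 = 1/T1 when a subject switches from breathing
air to a hyperoxic gas. Dissolved molecular oxygen is paramagnetic and raises
R1 in proportion to its tension; but so is deoxyhemoglobin, whose
concentration *falls* under hyperoxia, lowering blood R1. A voxel mixes both
effects in proportions set by its blood volume, so the measured ΔR1 can be
positive, negligible, or negative depending on tissue type. `hyperoxr1`
implements a three-compartment forward model — arterial blood, venous blood,
tissue — that predicts the voxel ΔR1 from five measurable quantities: field
strength B0, hematocrit (Hct), oxygen extraction fraction (OEF), blood volume
fraction (BV), and the critical tension of oxygen metabolism.

## The model, step by step

**Step 1 — capillary oxygen transport** (`capillary_profile()`). Total blood
oxygen content is the sum of dissolved and hemoglobin-bound oxygen,
c = α~p~·PO~2~ + Hct·c~0~·SO~2~, with saturation tied to tension by the Hill
curve SO~2~ = PO~2~^n^/(PO~2~^n^ + P50^n^). Extraction is assumed to
accumulate linearly along the capillary (the classical Kety picture). Two
decline modes are provided:

* `content_linear` (default): the *total content* falls linearly from the
  arterial value by the extracted amount, and (PO~2~, SO~2~) at each axial
  position are recovered by numerically inverting the content equation
  jointly with the Hill curve. This conserves oxygen exactly in every state.
  At normoxia it agrees with the classical formulation to within the
  dissolved share of content (~1.4% at 90 mmHg): the venous saturation for
  OEF = 0.34 is 0.6075 rather than SaO~2~(1−OEF) = 0.6051.
* `so2_linear`: the *saturation* falls linearly, so venous SO~2~ equals
  SaO~2~(1−OEF) exactly — the textbook bound-oxygen formulation. Under
  hyperoxia, where dissolved oxygen is ~8% of content, this mode does not
  conserve total oxygen, which is why it is not the default.

The hyperoxic profile reuses the *absolute* extraction (mlO~2~/ml) computed
from the normoxic OEF: tissue consumption is assumed unchanged by the gas
challenge, so the extraction, not the extraction *fraction*, carries over.

**Step 2 — tissue oxygenation** (`capillary_geometry()`, `tissue_field()`).
Each capillary (radius R~c~ = 3.5 µm, length L = 1 mm) supplies a coaxial
Krogh tissue cylinder. With capillaries on a √N×√N grid across the voxel
cross-section, the tissue radius follows from blood volume alone:
R~t~ = (R~c~/2)·√(π/BV), independent of voxel size. The maximum consumption
rate is fixed by mass balance over one cylinder in the normoxic state,
M~0~ = OEF·SaO~2~·Hct·c~0~·v·R~c~² / ((R~t~²−R~c~²)·L). The steady radial
tension profile is the Krogh–Erlang solution
PO~2~(r) = P~cap~ + (M/4K)(r²−R~c~²) − (M·R~t~²/2K)·ln(r/R~c~), with
K = D~T~·α~T~ the Krogh diffusion constant, and the uniform rate M replaced
by the Michaelis–Menten law M(PO~2~) = M~0~·PO~2~/(PO~2~+P~crit~) through a
fixed point on the slice-mean tension (see *Numerical choices*). Solving
every axial slice gives the tissue oxygen field; its volume-weighted mean in
the air and oxygen states yields ΔPO~2,T~.

**Step 3 — relaxometry** (`blood_r1()`, `oxygen_relaxivity()`). Blood R1 is
a two-compartment water mixture: the erythrocyte fraction
f~e~(Hct) = W~RBC~Hct/(W~RBC~Hct + W~plasma~(1−Hct)) relaxes at
R1~eox~ + r1~dHb~·[Hb]·(1−SO~2~), the plasma fraction at R1~p~ + r1~pOx~·PO~2~.
All four parameters are affine in B0. Tissue ΔR1 is r1~Ox~(B0,T)·ΔPO~2,T~
with the Lorentzian-plus-temperature relaxivity
r1~Ox~ = c~1~/(1+c~2~B0²) + c~3~ + c~temp~·T.

**Step 4 — voxel weighting** (`delta_r1_voxel()`). With equal arterial and
venous blood fractions by default,
ΔR1~voxel~ = (BV/2)·ΔR1~B,A~ + (1−BV)·ΔR1~T~ + (BV/2)·ΔR1~B,V~ — a convex
combination. Arterial blood is evaluated at the capillary entrance tensions,
venous blood at the exit tensions.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `p50_tissue`, `hill_n` | mmHg, – | 37, 2.7 | hemoglobin dissociation curve for transport |
| `alpha_p` | mlO~2~ ml^−1^ mmHg^−1^ | 3.1×10^−5^ | dissolved O~2~ in plasma |
| `c0` | mlO~2~ ml^−1^ | 0.5 | O~2~ capacity of saturated erythrocytes |
| `alpha_t`, `d_t` | –, m² s^−1^ | 2.8×10^−5^, 2.41×10^−9^ | tissue solubility and diffusivity (K = D~T~α~T~) |
| `cap_radius`, `cap_length`, `cap_velocity` | m, m, m s^−1^ | 3.5×10^−6^, 10^−3^, 7.9×10^−4^ | capillary geometry and flow |
| `w_rbc`, `w_plasma` | – | 0.70, 0.95 | water fractions entering f~e~ |
| `pao2_air`, `pao2_ox` | mmHg | 90, 600 | the standard hyperoxic gas challenge |
| `arterial_fraction` | – | 0.5 | equal arterial/venous split; exposed because real voxels differ |

`c0` is carried as an independent constant at its adopted literature value
0.5 mlO~2~/ml even though the Hüffner product C~Hb~·[Hb] = 1.36·0.43 = 0.585;
the loader flags the inconsistency rather than silently recomputing either.

Two Hill parameter sets coexist deliberately: the transport curve
(`p50_tissue`) and the blood relaxometry model's internal curve
(`p50_blood`), because the blood model may have been fitted with a different
dissociation curve. They default to the same values.

**Coefficients are inputs, not constants.** The eight blood-model
slope/intercepts and the four relaxivity constants come from separate fitted
relaxometry publications and are *not* hard-coded: they must be transcribed
into the configuration. The shipped placeholder set
(`placeholder_blood_coefficients()`,
`inst/extdata/placeholder_coefficients_synthetic.json`) is synthetic — built
once from public anchors (deoxyhemoglobin relaxivity ~0.11 s^−1^mM^−1^ at
1.5 T rising to ~0.35 at 4.7 T; plasma and erythrocyte R1 falling with
field; oxygen relaxivities in the published 1.5–4×10^−4^ s^−1^mmHg^−1^
envelope, decreasing in B0) — and every use emits a warning. Quantitative
predictions made with it demonstrate the machinery, not the physiology.

## Numerical choices

* **Content inversion.** The map PO~2~ → content is strictly increasing, so
  the inverse is unique; a safeguarded Newton iteration (analytic derivative
  α~p~ + Hct·c~0~·nS(1−S)/P, bisection fallback) drives the residual below
  10^−12^ mlO~2~/ml. `stats::uniroot` on the same residual serves as the
  independent cross-check in the tests.
* **Michaelis–Menten coupling.** The closed-form Krogh solution is exact
  only for uniform consumption. Each axial slice therefore uses one
  *effective* uniform rate, fixed-pointed on the volume-weighted slice mean:
  m ← M(mean PO~2~), stopping when successive means differ by <10^−6^ mmHg
  (cap 100 iterations, damping 0.5 on detected oscillation). Because tissue
  tensions in all presets sit far above P~crit~ (0.5–4 mmHg), M varies by
  ~1% across a slice and the fixed point converges in a handful of
  iterations. The tests compare this against a finite-volume boundary-value
  solve with fully spatially varying M; agreement is ~2×10^−3^ mmHg in mean
  tension, far inside the 0.5 mmHg acceptance band.
* **Grids.** Defaults n~z~ = 51 axial × n~r~ = 101 radial, uniform,
  endpoints inclusive; volume weights ∝ r·Δr·Δz (trapezoidal). Tensions are
  clamped at 0 with the clamped volume fraction reported, since the
  Krogh–Erlang form can go negative at large R~t~ and low capillary tension;
  no preset combination clamps.
* **Degenerate inputs.** BV = 1 skips the tissue path (pure blood);
  BV ≥ π/4 is rejected because the square-grid construction leaves no tissue
  annulus (R~t~ ≤ R~c~) — all preset tissue BVs (≤0.17) are far below this.
  Zero extraction gives a flat capillary profile; M~0~ = 0 a uniform tissue
  field; a null challenge returns exactly zero everywhere. Capillary counts
  stay continuous (no rounding) to avoid discretisation steps in sweeps.
* **Sweep sizes.** The factorial sweeps default to 5 points per varying
  range; the sex-stratified comparison in the acceptance script uses 3
  points per range and reduced tissue grids (n~z~ = 21, n~r~ = 51), which
  changes preset-mean ΔR1 by well under the differences being compared.

## What the scenario generator emulates — and what it does not

`random_scenario()` draws uniformly within a preset's published ranges
(hematocrit 0.36–0.50 total, preset OEF/BV/P~crit~ ranges, fields from
{1.5, 3, 4.7, 7} T). That reproduces the *study conditions*: parameter
boxes, not population structure. It does not model correlations between Hct
and OEF, measurement noise, partial-volume mixtures of tissue types, or
intra-voxel heterogeneity — so passing property tests show the model behaves
correctly across the stated ranges, not that real tumours sample those
ranges uniformly.

## Design decisions taken where the construction was open

* The voxel-width relation is implemented as voxel_width = 2R~t~·√N~cap~
  (capillaries spaced evenly across *both* cross-sectional directions); the
  linear-in-N~cap~ variant is dimensionally inconsistent with that
  arrangement.
* M~0~ is derived from the per-cylinder mass balance
  v·πR~c~²·Hct·c~0~·SaO~2~·OEF = M~0~·π(R~t~²−R~c~²)·L, the form that
  conserves oxygen and is dimensionally consistent; it is linear in OEF and
  reduces to the linear saturation decline matching the capillary-mean
  relation SO~2,mean~ = SaO~2~(1−OEF/2) at mid-capillary.
* ΔPO~2,T~ entering the tissue relaxometry is the *volume-weighted mean*
  field difference; the field minimum (at r = R~t~, z = L) is reported as a
  diagnostic instead.
* The hyperoxic capillary state is content-linear by default (mass balance),
  with the saturation-linear mode behind a flag for comparison with the
  classical formulation.

## Known limitations

* All Krogh assumptions apply: parallel, unbranched, evenly spaced
  capillaries, no axial tissue diffusion, steady state. Tumour vasculature
  violates these; the module boundary is deliberately clean so another
  tissue-oxygenation model can replace Step 2.
* No Bohr/Haldane shifts of the dissociation curve, no R2/R2* effects, no
  exchange-regime corrections.
* The derived-quantity envelopes differ from some published summary ranges:
  over the preset grids this implementation gives R~t~ from 7.5×10^−6^ m
  (BV 0.17) to 9.8×10^−5^ m (BV 0.001) and M~0~ from 3.9×10^−6^ to
  8.4×10^−3^ mlO~2~ ml^−1^ s^−1^, versus reported ranges of
  1.07–4.43×10^−5^ m and 1.2×10^−5^–3.5×10^−4^. Neither published range is
  reproducible from the stated constructions for the full preset grids, so
  the comparison is logged, not asserted.
* With the synthetic placeholder coefficients the predicted tissue-type
  ranking at 1.5 T places necrotic tissue (ΔR1 ≈ 0.125 s^−1^) above the
  pure-blood vascular periphery (≈0.027 s^−1^): an avascular voxel with
  near-zero extraction tracks the full ~400 mmHg mean capillary tension
  change, and any oxygen relaxivity in the published envelope then outweighs
  the blood compartment average. The reported empirical ranking (periphery
  above necrotic) therefore hinges on the transcribed coefficient
  magnitudes — particularly a plasma-oxygen relaxivity well above the
  placeholder value — and is not reproduced by the placeholder set. The
  venous sign (negative ΔR1 at venous saturations) and the
  necrotic-above-hypoxic-core ordering are robust to the placeholder choice.

## A worked example

```{r, eval = FALSE}
library(hyperoxr1)

blood <- placeholder_blood_coefficients()   # warns: synthetic, testing only
relax <- placeholder_relaxivity_coefficients()

scn <- scenario(b0 = 1.5, hct = 0.43, oef = 0.34, bv = 0.045, p_crit = 2.5,
                tissue_type = "healthy_brain")
res <- run_scenario(scn, blood_coeffs = blood, relax_coeffs = relax)
res
tidy(res)

sw <- run_sweep("hypoxic_high_bv", b0 = c(1.5, 3), steps = 3,
                blood_coeffs = blood, relax_coeffs = relax)
plot_sweep(sw, "oef")

sex_comparison(b0 = c(1.5, 3, 4.7, 7), steps = 3,
               blood_coeffs = blood, relax_coeffs = relax)
```
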