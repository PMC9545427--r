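# hyperoxr1

Forward modelling of hyperoxia-induced changes in the longitudinal
relaxation rate R1 of tissue voxels, for oxygen-enhanced MRI (OE-MRI)
research.

Breathing a hyperoxic gas raises the oxygen tension PO₂ throughout the
vasculature and tissue. Dissolved O₂ is paramagnetic and raises R1 = 1/T1;
falling deoxyhemoglobin *lowers* blood R1 at the same time. Whether an
imaging voxel shows a positive, negligible or negative ΔR1 therefore depends
on its blood volume, hematocrit, oxygen extraction and field strength —
which is exactly what this package computes, for users who want to predict
or interpret OE-MRI contrast in healthy tissue and tumour compartments.

## The model

A voxel is three compartments — arterial blood, venous blood, tissue —
evaluated in four steps:

1. **Capillary oxygen transport.** Total content c = α_p·PO₂ + Hct·c₀·SO₂
   with the Hill curve SO₂ = PO₂ⁿ/(PO₂ⁿ + P50ⁿ); extraction accumulates
   linearly along the capillary. The hyperoxic state reuses the *absolute*
   extraction fixed by the normoxic oxygen extraction fraction (OEF).
2. **Krogh cylinder tissue oxygenation.** Tissue radius from blood volume,
   R_t = (R_c/2)·√(π/BV); maximum consumption from mass balance,
   M₀ = OEF·SaO₂·Hct·c₀·v·R_c²/((R_t²−R_c²)·L); radial tension from the
   Krogh–Erlang solution with Michaelis–Menten consumption
   M(PO₂) = M₀·PO₂/(PO₂+P_crit).
3. **Relaxometry.** Blood R1 from a two-compartment erythrocyte/plasma
   model, R1_b = f_e(R1_eox + r1_dHb·[Hb]·(1−SO₂)) + (1−f_e)(R1_p +
   r1_pOx·PO₂), all four parameters affine in B0; tissue
   ΔR1_T = r1_Ox(B0,T)·ΔPO₂_T with a Lorentzian field dependence for r1_Ox.
4. **Voxel weighting.** ΔR1_voxel = (BV/2)·ΔR1_B,A + (1−BV)·ΔR1_T +
   (BV/2)·ΔR1_B,V.

Six tissue-type presets ship with the package (healthy brain, tumour
vascular periphery, hypoxic tumour at low/high blood volume, normally
metabolising tumour, necrotic tissue), plus factorial sweeps over their
published parameter ranges and a sex-stratified hematocrit comparison.

The fitted blood-model and oxygen-relaxivity coefficients come from separate
relaxometry publications and are **configuration inputs**, not package
constants. A clearly labelled synthetic placeholder set is included for
testing; every use warns.

## Worked example

```r
library(hyperoxr1)

blood <- placeholder_blood_coefficients()   # warns: synthetic, testing only
relax <- placeholder_relaxivity_coefficients()

scn <- scenario(b0 = 1.5, hct = 0.43, oef = 0.34, bv = 0.045, p_crit = 2.5,
                tissue_type = "healthy_brain")
run_scenario(scn, blood_coeffs = blood, relax_coeffs = relax)
#> <voxel_result> healthy_brain at 1.5 T (Hct 0.43, OEF 0.34, BV 0.045, PaO2 90 -> 600 mmHg)
#>   dR1 arterial +0.08287  venous -0.02930  tissue +0.02848  voxel +0.02841 s^-1
#>   tissue dPO2 92.480 mmHg, venous PO2 43.49 -> 56.89 mmHg
```

Read: on switching from air (arterial PO₂ 90 mmHg) to oxygen (600 mmHg),
arterial blood R1 rises by 0.083 s⁻¹ (dissolved O₂ wins), venous blood R1
*falls* by 0.029 s⁻¹ (deoxyhemoglobin wins at venous saturations — the
venous tension only moves 43 → 57 mmHg because extraction is unchanged), and
the tissue, whose mean tension rises 92 mmHg, gains 0.028 s⁻¹. Weighted by a
4.5% blood volume the voxel shows ΔR1 = +0.028 s⁻¹ — the tissue term
dominates, as expected for low-blood-volume voxels.

Sweeps and the sex comparison chain the same machinery:

```r
sw <- run_sweep("hypoxic_high_bv", b0 = c(1.5, 3), steps = 3,
                blood_coeffs = blood, relax_coeffs = relax)
plot_sweep(sw, "oef")
sex_comparison(b0 = c(1.5, 3, 4.7, 7), steps = 3,
               blood_coeffs = blood, relax_coeffs = relax)
```

A thin command-line interface wraps the same functions
(`inst/cli/hyperoxr1.R`, subcommands `run`, `sweep`, `presets`, `constants`,
`validate`); every invocation writes its result CSV plus a JSON manifest
recording coefficient provenance.

See `vignettes/voxel-deltaR1-model.Rmd` for the full account of the model,
its numerical choices and its limitations.

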