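{
  "_comment": "Configuration schema for hyperoxr1. All keys lower_snake_case. A config file is a JSON object with up to four sections; every field is optional unless marked required.",
  "constants": {
    "p50_tissue": "hemoglobin half-saturation tension for capillary/tissue transport, mmHg (default 37)",
    "hill_n": "Hill exponent, unitless (default 2.7)",
    "alpha_p": "plasma O2 solubility, mlO2 ml^-1 mmHg^-1 (default 3.1e-5)",
    "c_hb": "Huffner factor, mlO2 g^-1 (default 1.36)",
    "c0": "O2 capacity per unit erythrocyte volume at full saturation, mlO2 ml^-1 (default 0.5)",
    "hb_molar": "mean corpuscular hemoglobin concentration, mmol tetramer L^-1 (default 5.15)",
    "hb_mass": "mean corpuscular hemoglobin concentration, g mL^-1 (default 0.43)",
    "alpha_t": "tissue O2 solubility, mlO2 ml^-1 mmHg^-1 (default 2.8e-5)",
    "d_t": "tissue O2 diffusivity, m^2 s^-1 (default 2.41e-9)",
    "cap_length": "capillary length, m (default 0.001)",
    "cap_radius": "capillary radius, m (default 3.5e-6)",
    "cap_velocity": "capillary blood velocity, m s^-1 (default 7.9e-4)",
    "w_rbc": "erythrocyte water volume fraction, 0-1 (default 0.70)",
    "w_plasma": "plasma water volume fraction, 0-1 (default 0.95)",
    "temperature": "tissue temperature, degC (default 37)"
  },
  "blood_coefficients": {
    "r1eox_b0": "REQUIRED intercept of R1eox(B0), s^-1",
    "r1eox_b1": "REQUIRED slope of R1eox(B0), s^-1 T^-1",
    "r1p_b0": "REQUIRED intercept of R1p(B0), s^-1",
    "r1p_b1": "REQUIRED slope of R1p(B0), s^-1 T^-1",
    "r1dhb_b0": "REQUIRED intercept of r1dHb(B0), s^-1 L mmol^-1",
    "r1dhb_b1": "REQUIRED slope of r1dHb(B0), s^-1 L mmol^-1 T^-1",
    "r1pox_b0": "REQUIRED intercept of r1pOx(B0), s^-1 mmHg^-1",
    "r1pox_b1": "REQUIRED slope of r1pOx(B0), s^-1 mmHg^-1 T^-1",
    "p50_blood": "half-saturation tension of the blood-model Hill curve, mmHg (default 37)",
    "hill_n_blood": "Hill exponent of the blood-model curve (default 2.7)",
    "provenance": "free text, e.g. 'user'; placeholder sets are marked 'placeholder'"
  },
  "relaxivity_coefficients": {
    "c1": "REQUIRED Lorentzian amplitude, s^-1 mmHg^-1",
    "c2": "REQUIRED Lorentzian width coefficient, T^-2",
    "c3": "REQUIRED field-independent offset, s^-1 mmHg^-1",
    "c_temp": "REQUIRED temperature slope, s^-1 mmHg^-1 degC^-1",
    "provenance": "free text as above"
  },
  "scenario": {
    "b0": "main magnetic field, T",
    "hct": "hematocrit, 0-1",
    "oef": "oxygen extraction fraction, 0-1",
    "bv": "blood volume fraction, 0-1",
    "p_crit": "critical tension, mmHg",
    "pao2_air": "arterial PO2 breathing air, mmHg (default 90)",
    "pao2_ox": "arterial PO2 on the hyperoxic gas, mmHg (default 600)",
    "arterial_fraction": "arterial share of blood volume, 0-1 (default 0.5)",
    "tissue_type": "label or preset name"
  }
}
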