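# Design I preset: crystalline weak acid buffered with CaCO3.
# The buffer raises the gastric pH to 7-8, allowing early gastric dissolution;
# the Ca2+ counter-ion salts the drug out, capping solubility.
formulation_id: buffered_crystal
dose_mg: 80
api_form: crystal
buffered: true
pKa: 4.33
intrinsic_solubility_mg_per_mL: 0.001
dissolution_rate_coeff_z: 0.05
disintegration_time_min: 3
solubility_ceiling_mg_per_mL: 0.3
gastric_ph_after_buffer: 7.5
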