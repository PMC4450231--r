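# Design II preset: amorphous weak acid, no buffering agent.
# The stomach stays at pH 2.4, where a pKa 4.33 weak acid is essentially
# insoluble, so no drug dissolves before gastric emptying.
formulation_id: nonbuffered_amorphous
dose_mg: 80
api_form: amorphous
buffered: false
pKa: 4.33
intrinsic_solubility_mg_per_mL: 0.002
dissolution_rate_coeff_z: 0.2
disintegration_time_min: 3
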