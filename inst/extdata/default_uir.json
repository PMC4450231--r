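{"dose_basis_mg": 80, "terms": [{"C": 120, "lambda": 2.0}, {"C": 30, "lambda": 0.25}]}
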