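# reference design: enrichment trial with an imperfect diagnostic
n_per_arm: 240
ppv: 0.75
hr_pos: 0.7
hr_neg: 1.26
censor_rate: 0.3
seed: 42
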