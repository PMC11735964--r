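name: scenario2_spike
dose_scenario: 2
spike: true
"N": 1000
M: 500
seed: 103
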