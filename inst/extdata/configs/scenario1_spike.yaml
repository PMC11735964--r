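name: scenario1_spike
dose_scenario: 1
spike: true
"N": 1000
M: 500
seed: 101
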