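# Preclinical trial preset: CU participants, two visits 54 months apart
group: CU
visit_times: [0.0, 4.5]
power: 0.80
alpha: 0.05
pct_change: 0.20
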