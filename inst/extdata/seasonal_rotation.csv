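season,fruit_delta,vegetable_delta,grain_delta
1,-0.04,-0.04,0.08
2,0.00,0.04,-0.04
3,0.05,0.03,-0.08
4,0.02,0.01,-0.03
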