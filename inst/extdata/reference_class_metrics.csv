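class,precision,recall,support
Mediterranean,0.522,0.112,107
Western,0.396,0.304,125
Plant-based,0.500,0.063,64
Mixed,0.378,0.792,154
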