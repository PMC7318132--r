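site	rate_per_min
6β	83
2β	11
15β	5.0
1β	4.8
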