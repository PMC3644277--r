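well_id	nutrients	growth_call
W1	A,B,F	growth
W2	A,F	no-growth
W3	B,F	low-growth
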