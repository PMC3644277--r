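# minnut-model	v1
compound	C1		instance	
compound	C2		instance	
compound	N1		instance	
compound	N2		instance	
compound	M		instance	
reaction	R1	C1 + N1 -> M	
reaction	R2	C2 + N2 -> M	
transportable	C1
transportable	C2
transportable	N1
transportable	N2
biomass	M
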