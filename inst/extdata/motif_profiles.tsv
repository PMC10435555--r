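domain	idx	pattern
RT	1	KLLPQGMKG
RT	2	VQYMDDILL
RH	1	IHTDGSSFV
IN	1	HSDNGPAFV
TM	1	
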