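iop_min	iop_max	age_min	age_max	cct_min	cct_max	treat
30	Inf	-Inf	Inf	-Inf	Inf	TRUE
28	30	-Inf	80	-Inf	Inf	TRUE
26	28	-Inf	80	-Inf	555	TRUE
24	26	-Inf	55	-Inf	555	TRUE
-Inf	Inf	-Inf	Inf	-Inf	Inf	FALSE
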