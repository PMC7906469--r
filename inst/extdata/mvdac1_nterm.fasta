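>mVDAC1_Nterm_M1-G25 murine VDAC1 N-terminal segment (crystal structure 3EMN)
MAVPPTYADLGKSARDVFTKGYGFG
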