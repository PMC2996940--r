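domain	clan
PF00001	CL0001
PF00002	CL0001
PF00003	CL0002
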