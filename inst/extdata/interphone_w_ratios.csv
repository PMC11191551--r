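exposure,level,w_control,w_case
nonregular,nonregular,0.70,0.71
regular,>=2001,0.84,0.90
regular,1998-2000,1.39,1.05
regular,1993-1997,1.91,1.97
regular,<=1992,1.72,1.32
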