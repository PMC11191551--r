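exposure,level,control,case
nonregular,nonregular,0.67,0.93
regular,>=2001,0.70,0.94
regular,1998-2000,0.80,0.95
regular,1993-1997,0.84,0.97
regular,<=1992,0.83,0.96
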