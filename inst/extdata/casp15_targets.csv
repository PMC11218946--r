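target_id,length_nt,target_class,difficulty
R1107,69,natural,medium
R1108,69,natural,medium
R1116,157,natural,difficult
R1117,30,natural,easy
R1126,363,synthetic,synthetic
R1128,238,synthetic,synthetic
R1136,374,synthetic,synthetic
R1138,720,synthetic,synthetic
R1149,124,natural,difficult
R1156,135,natural,difficult
R1189,118,natural,difficult
R1190,118,natural,difficult
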