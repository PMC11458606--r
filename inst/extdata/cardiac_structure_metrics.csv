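structure,dsc,miou,recall,precision
CS,0.88,0.87,0.97,0.99
DA,0.94,0.96,0.94,0.98
IVC,0.96,0.90,0.97,0.99
LAA,0.89,0.88,0.98,0.99
LAW,0.82,0.84,0.95,0.99
PM,0.84,0.87,0.92,0.97
PML,0.81,0.79,0.94,0.97
PAA,0.96,0.98,0.98,0.99
PA,0.99,0.98,0.99,0.98
RVW,0.98,0.92,0.99,0.98
SVC,0.95,0.94,0.98,0.99
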