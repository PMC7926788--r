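# Synthetic stand-in for the fatty-acid ligand exclusion table.
# One chemical-component code per line; codes in this list are
# purged from any negative evaluation pool.
PLM
MYR
OLA
STE
DAO
DKA
OCA
HXA
LAU
EPA
ELA
PAE
ARA
LNL
MLR
SAC
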