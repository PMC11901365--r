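# SYNTHETIC stand-in table for an additive per-residue unfolding model:
# dG_i = dH_i - T * dS_i (T = 298.15 K default). The published per-residue
# tabulation is not redistributed here; replace this file (same schema) to
# use experimentally derived constants.
residue,dH_kJ_mol,dS_kJ_mol_K
A,159.48,0.4175
C,183.71,0.4317
D,114.41,0.3502
E,98.54,0.2802
F,168.69,0.1633
G,118.14,0.4298
H,108.02,0.1946
I,217.72,0.3613
K,69.84,0.1504
L,218.24,0.3798
M,196.72,0.3747
N,142.5,0.4377
P,40.25,0.2524
Q,72.09,0.1747
R,133.92,0.315
S,125.89,0.439
T,99.66,0.2739
V,160.54,0.2366
W,266.95,0.4258
Y,159.1,0.215
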