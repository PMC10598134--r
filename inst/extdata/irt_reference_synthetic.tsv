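# SYNTHETIC reference values for the 11 public iRT peptide sequences.
# 1/K0 computed from evenly spaced CCS values (320-430 A^2, z=2) via Mason-Schamp at T = 305 K;
# NOT measured values. Replace with your own reference table for real data.
sequence	ref_inv_k0	ref_rt	charge
LGGNEQVTR	0.78776	10	2
YILAGVENSK	0.81609	20	2
GTFIIDPGGVIR	0.84449	30	2
GTFIIDPAAVIR	0.87187	40	2
GAGSSEPVTGLDAK	0.89916	50	2
TPVISGGPYEYR	0.9267	60	2
VEATFGVDESNAK	0.95408	70	2
TPVITGAPYEYR	0.98127	80	2
DGLDAASYYAPVR	1.00868	90	2
ADVTPADFSEWSK	1.03626	100	2
LFLQFGAQGSPFLK	1.06411	110	2
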