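# ambientglu AMPAR 13-state rate table (calibrated default)
# units: time ms, concentration uM; rate /ms (ligand_order 0) or /ms/uM (ligand_order 1)
# T_ref_C: 23
# Q10: 2.4
# g_max_nS: 5
# open_conductance: O1=1,O2=1,O3=1,O4=1
from	to	rate	ligand_order
C0	C1	0.080000000000000002	1
C1	C2	0.059999999999999998	1
C2	C3	0.040000000000000001	1
C3	C4	0.02	1
C1	C0	2.3999999999999999	0
C2	C1	4.7999999999999998	0
C3	C2	7.1999999999999993	0
C4	C3	9.5999999999999996	0
C1	O1	1	0
C2	O2	1	0
C3	O3	1	0
C4	O4	1	0
O1	C1	2	0
O2	C2	2	0
O3	C3	2	0
O4	C4	2	0
C1	D1	0.1623679668572518	0
C2	D2	0.1623679668572518	0
D1	C1	0.050000000000000003	0
D2	C2	0.050000000000000003	0
C3	D3	0.053380847524459561	0
C4	D4	0.053380847524459561	0
D3	C3	0.0040000000000000001	0
D4	C4	0.0040000000000000001	0
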