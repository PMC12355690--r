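param	ff_type	r0	d0
lj	H_	3.195	0.0152
lj	H__HB	3.195	0.0001
lj	C_3	3.8983	0.0951
lj	C_R	3.8983	0.0951
lj	C_2	3.8983	0.0951
lj	C_1	3.8983	0.0951
lj	N_3	3.6621	0.0774
lj	N_R	3.6621	0.0774
lj	N_2	3.6621	0.0774
lj	N_1	3.6621	0.0774
lj	O_3	3.4046	0.0957
lj	O_R	3.4046	0.0957
lj	O_2	3.4046	0.0957
lj	F_	3.472	0.0725
lj	S_3	4.03	0.344
lj	Cl	3.9503	0.2833
lj	Br	3.95	0.37
lj	I_	4.15	0.51
lj	Ar	3.868	0.185
hbond		2.75	9.5
dielectric		1	0
combining	geometric	0	0
hb_window		4.5	90
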