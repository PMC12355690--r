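descriptor	window
s_axis	2.0
s_over_l	0.20
m_over_l	0.25
no_fraction	0.20
dipole	6.0
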