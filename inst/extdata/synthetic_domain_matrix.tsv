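gene	GC.BR_36v	OR.b_36v	OR.a_36v	VP_36l	AV_36l	AD_36l	PD_36l	PV_36l	GCL_52v	INL.b_52v	INL.m_52v	INL.a_52v	ONL_52v	VP_52l	AV_52l	AD_52l	PD_52l	PV_52l
gene01	0	0	0	0	0	0	0	0	0	0	0	0	1	1	0	0	0	0
gene02	0	0	0	0	0	0	0	0	1	0	0	0	1	1	0	0	0	0
gene03	0	0	0	0	0	0	0	0	0	0	1	0	1	1	0	0	0	0
gene04	0	0	0	0	0	0	0	0	0	0	0	0	1	1	0	0	0	0
gene05	0	0	0	0	0	0	0	0	0	0	0	0	1	1	0	0	0	0
gene06	0	0	0	0	0	0	0	0	0	0	0	0	1	1	0	0	0	0
gene07	0	0	0	0	0	0	0	1	0	0	0	0	1	1	0	0	0	0
gene08	0	0	0	0	0	0	1	0	0	0	0	0	1	1	0	0	0	0
gene09	1	0	0	1	1	1	0	0	1	1	0	0	0	1	1	1	1	0
gene10	1	0	0	1	1	1	0	0	1	1	0	0	0	1	1	1	1	0
gene11	1	0	0	1	1	1	0	0	1	1	0	0	0	1	1	1	1	0
gene12	1	0	0	1	1	1	0	0	1	1	0	0	0	1	1	1	1	0
gene13	1	0	0	1	1	1	0	0	1	1	0	1	0	1	1	1	1	0
gene14	0	0	0	0	0	0	0	0	1	1	1	1	0	0	1	1	1	1
gene15	0	0	0	0	0	0	0	0	1	1	1	1	0	0	1	1	1	1
gene16	0	0	0	0	0	0	0	0	1	1	0	1	0	0	0	1	1	1
gene17	0	0	0	0	0	0	0	0	1	1	1	1	0	0	1	1	1	1
gene18	0	0	0	0	0	0	0	0	1	1	1	1	0	0	1	1	1	1
gene19	0	0	0	0	0	0	0	0	1	1	1	1	0	0	1	1	1	1
gene20	0	0	0	0	0	0	0	0	1	1	1	1	0	0	1	1	1	1
gene21	0	0	0	0	0	0	0	0	1	1	1	1	0	0	1	1	1	1
gene22	0	0	0	0	0	0	0	0	1	1	1	1	0	0	1	1	1	1
gene23	0	0	0	0	0	0	0	0	1	1	1	1	1	0	1	1	1	1
gene24	0	0	0	0	0	0	0	0	1	1	1	1	0	0	1	1	1	1
gene25	0	0	0	0	0	0	0	0	0	1	1	1	0	0	1	1	1	1
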