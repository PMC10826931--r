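C0011892	0.12	-0.40	0.33	0.05	-0.21
C0600290	0.52	0.11	-0.08	0.40	0.02
C0027358	-0.30	0.27	0.19	-0.14	0.44
C0015846	0.08	-0.09	0.51	0.22	-0.35
C0856054	-0.11	0.06	-0.27	0.31	0.18
C0235063	0.21	0.38	0.04	-0.42	-0.07
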