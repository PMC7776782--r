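assay	group	mean_mf
duplex_sequencing	VC	1.48e-7
duplex_sequencing	BaP	1.16e-6
duplex_sequencing	ENU	1.27e-6
plaque_assay	VC	4.09e-5
plaque_assay	BaP	4.42e-4
plaque_assay	ENU	3.06e-4
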