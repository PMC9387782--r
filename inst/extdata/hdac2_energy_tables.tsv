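set	ligand	dE_vdw	dE_elec	dG_polar	dG_nonpolar	dG_pbsa	minus_TdS	dG_total
known	LLX	-33.30	-112.99	80.06	-3.86	-70.08	5.84	-64.24
known	SAHA	-26.27	-103.15	58.62	-3.37	-74.16	16.32	-57.84
known	20Y	-38.34	-117.77	84.07	-4.37	-76.42	10.96	-65.46
known	IWX	-39.34	-101.20	80.91	-3.98	-63.62	2.75	-60.87
known	6EZ	-42.82	-101.46	79.20	-4.36	-69.44	6.74	-62.70
carbamide	1	-35.80	-95.61	73.21	-3.80	-62.00	5.88	-56.12
carbamide	2	-34.62	-88.20	66.92	-3.45	-59.34	6.57	-52.77
carbamide	3	-34.78	-86.39	66.96	-3.54	-57.75	7.08	-50.67
carbamide	4	-33.53	-90.26	70.51	-3.72	-53.46	7.60	-45.86
carbamide	5	-23.39	-98.22	90.89	-3.03	-33.75	5.64	-28.11
carbamide	6	-21.77	-97.43	104.25	-2.62	-17.57	6.07	-11.49
carbamide	7	-25.85	-95.54	108.19	-2.98	-16.17	5.75	-10.42
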