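gene	condition	substantial	yield_fraction
MYBPC3	HCM	TRUE	0.40
MYH7	HCM	TRUE	0.30
FHL1	HCM	FALSE	0.01
DMD	DCM	TRUE	0.05
MYH7	DCM	FALSE	0.04
KCNQ1	LQTS	TRUE	0.35
SCN10A	BRUGADA	FALSE	NA
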