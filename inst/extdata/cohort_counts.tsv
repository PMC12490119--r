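analysis	cohort	asd	preterm	n
phenotype	spark	yes	yes	9196
phenotype	spark	yes	no	65021
phenotype	spark	no	yes	2706
dnv_wgs	spark	yes	yes	309
dnv_wgs	spark	yes	no	2728
dnv_wgs	spark	no	yes	164
dnv_wes	spark	yes	yes	697
dnv_wes	spark	yes	no	5747
dnv_wes	spark	no	yes	210
inherited	spark	yes	yes	310
inherited	spark	yes	no	2742
inherited	spark	no	yes	165
prs	spark	yes	yes	305
prs	spark	yes	no	2702
prs	spark	no	yes	161
phenotype	ssc	yes	yes	157
phenotype	ssc	yes	no	1479
dnv_wgs	ssc	yes	yes	137
dnv_wgs	ssc	yes	no	1313
prs	ssc	yes	yes	155
prs	ssc	yes	no	1435
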