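# Per-domain active-site fingerprints of the ossamycin PKS multienzymes
# OssA1-OssA8, transcribed from the published domain-by-domain analysis.
# Columns: at_ser4/at_sec = AT serine and second-His motifs; dh_his/dh_asp =
# the essential His of Hxxx(G/D)xxxxPG and Asp of Dxxx(Q/H); kr_* = the
# LDD-motif, A-type Trp, His-for-Gln (A2), and catalytic Lys/Ser/Tyr
# residues; er_tyr = the ER Tyr-motif residue; ksq = the KS active-site
# Cys (extension) or Gln (decarboxylating loading domain).
protein	domain_type	ksq	at_ser4	at_sec	dh_his	dh_asp	kr_ldd	kr_trp	kr_qh	kr_lys	kr_ser	kr_tyr	er_tyr
OssA1	KSQ	Q	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA1	AT	NA	GHSI	YASH	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA1	ACP	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA1	KS	C	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA1	AT	NA	GHSI	YASH	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA1	DH	NA	NA	NA	R	D	NA	NA	NA	NA	NA	NA	NA
OssA1	KR	NA	NA	NA	NA	NA	LDD	L	Q	K	S	Y	NA
OssA1	ACP	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA1	KS	C	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA1	AT	NA	GHSI	YASH	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA1	KR	NA	NA	NA	NA	NA	AGA	W	Q	K	S	Y	NA
OssA1	ACP	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA2	KS	C	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA2	AT	NA	GHSQ	HAFH	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA2	DH	NA	NA	NA	H	D	NA	NA	NA	NA	NA	NA	NA
OssA2	ER	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	Y
OssA2	KR	NA	NA	NA	NA	NA	LDD	L	Q	K	S	Y	NA
OssA2	ACP	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA2	KS	C	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA2	AT	NA	GHSV	YASH	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA2	ACP	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA3	KS	C	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA3	AT	NA	GHSQ	HAFH	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA3	KR	NA	NA	NA	NA	NA	LDD	L	Q	K	S	Y	NA
OssA3	ACP	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA3	KS	C	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA3	AT	NA	GHSL	YASH	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA3	KR	NA	NA	NA	NA	NA	AGA	W	H	K	S	Y	NA
OssA3	ACP	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA3	KS	C	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA3	AT	NA	GHSV	SPGH	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA3	DH	NA	NA	NA	Y	D	NA	NA	NA	NA	NA	NA	NA
OssA3	ACP	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA4	KS	C	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA4	AT	NA	GHSQ	HAFH	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA4	DH	NA	NA	NA	H	D	NA	NA	NA	NA	NA	NA	NA
OssA4	KR	NA	NA	NA	NA	NA	LDD	L	Q	K	S	Y	NA
OssA4	ACP	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA5	KS	C	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA5	AT	NA	GHSQ	HAFH	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA5	DH	NA	NA	NA	H	D	NA	NA	NA	NA	NA	NA	NA
OssA5	ER	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	Y
OssA5	KR	NA	NA	NA	NA	NA	LDD	L	Q	K	S	Y	NA
OssA5	ACP	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA6	KS	C	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA6	AT	NA	GHSI	YASH	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA6	DH	NA	NA	NA	H	D	NA	NA	NA	NA	NA	NA	NA
OssA6	ER	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	Y
OssA6	KR	NA	NA	NA	NA	NA	LDD	L	Q	K	S	Y	NA
OssA6	ACP	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA7	KS	C	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA7	AT	NA	GHSQ	HAFH	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA7	DH	NA	NA	NA	H	D	NA	NA	NA	NA	NA	NA	NA
OssA7	ER	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	Y
OssA7	KR	NA	NA	NA	NA	NA	LDD	L	Q	K	S	Y	NA
OssA7	ACP	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA7	KS	C	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA7	AT	NA	GHSQ	HAFH	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA7	DH	NA	NA	NA	H	D	NA	NA	NA	NA	NA	NA	NA
OssA7	ER	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	Y
OssA7	KR	NA	NA	NA	NA	NA	LDD	L	Q	K	S	Y	NA
OssA7	ACP	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA8	KS	C	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA8	AT	NA	GHSQ	HAFH	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA8	KR	NA	NA	NA	NA	NA	AGA	W	Q	K	S	Y	NA
OssA8	ACP	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA8	KS	C	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA8	AT	NA	GHSI	YASH	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA8	KR	NA	NA	NA	NA	NA	LDD	L	Q	K	S	Y	NA
OssA8	ACP	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
OssA8	TE	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
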