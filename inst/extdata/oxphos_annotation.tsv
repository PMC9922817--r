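# Human OXPHOS subunit annotation, compiled from standard human subunit
# lists and published assembly models. Totals: CI 45, CII 4, CIII 11,
# CIV 21, CV 17; 13 mitochondrial-encoded entries. CI follows the
# seven-module architecture (N, Q, ND1, ND2, ND4, ND5, NDUFAB1); CIII/CIV
# use assembly subcomplexes, CV assembly steps. Entries whose membership or
# module placement is not firmly established (tissue isoforms, the UQCRFS1
# presequence, historically reassigned subunits) carry uncertain = 1.
protein_id	gene	encoding	complex	module	uncertain
MT-ND1	MT-ND1	mitochondrial	CI	ND1	0
MT-ND2	MT-ND2	mitochondrial	CI	ND2	0
MT-ND3	MT-ND3	mitochondrial	CI	ND2	0
MT-ND4	MT-ND4	mitochondrial	CI	ND4	0
MT-ND4L	MT-ND4L	mitochondrial	CI	ND2	0
MT-ND5	MT-ND5	mitochondrial	CI	ND5	0
MT-ND6	MT-ND6	mitochondrial	CI	ND2	0
NDUFV1	NDUFV1	nuclear	CI	N	0
NDUFV2	NDUFV2	nuclear	CI	N	0
NDUFV3	NDUFV3	nuclear	CI	N	0
NDUFS1	NDUFS1	nuclear	CI	N	0
NDUFS4	NDUFS4	nuclear	CI	N	0
NDUFS6	NDUFS6	nuclear	CI	N	0
NDUFA2	NDUFA2	nuclear	CI	N	0
NDUFA6	NDUFA6	nuclear	CI	N	0
NDUFA7	NDUFA7	nuclear	CI	N	0
NDUFA12	NDUFA12	nuclear	CI	N	0
NDUFA4	NDUFA4	nuclear	CI	N	1
NDUFS2	NDUFS2	nuclear	CI	Q	0
NDUFS3	NDUFS3	nuclear	CI	Q	0
NDUFS7	NDUFS7	nuclear	CI	Q	0
NDUFS8	NDUFS8	nuclear	CI	Q	0
NDUFA5	NDUFA5	nuclear	CI	Q	0
NDUFA3	NDUFA3	nuclear	CI	ND1	0
NDUFA8	NDUFA8	nuclear	CI	ND1	0
NDUFA13	NDUFA13	nuclear	CI	ND1	0
NDUFA9	NDUFA9	nuclear	CI	ND1	1
NDUFC1	NDUFC1	nuclear	CI	ND2	0
NDUFC2	NDUFC2	nuclear	CI	ND2	0
NDUFA1	NDUFA1	nuclear	CI	ND2	0
NDUFA10	NDUFA10	nuclear	CI	ND2	0
NDUFS5	NDUFS5	nuclear	CI	ND2	0
NDUFB1	NDUFB1	nuclear	CI	ND4	0
NDUFB4	NDUFB4	nuclear	CI	ND4	0
NDUFB5	NDUFB5	nuclear	CI	ND4	0
NDUFB6	NDUFB6	nuclear	CI	ND4	0
NDUFB10	NDUFB10	nuclear	CI	ND4	0
NDUFB11	NDUFB11	nuclear	CI	ND4	0
NDUFA11	NDUFA11	nuclear	CI	ND4	1
NDUFB2	NDUFB2	nuclear	CI	ND5	0
NDUFB3	NDUFB3	nuclear	CI	ND5	0
NDUFB7	NDUFB7	nuclear	CI	ND5	0
NDUFB8	NDUFB8	nuclear	CI	ND5	0
NDUFB9	NDUFB9	nuclear	CI	ND5	0
NDUFAB1	NDUFAB1	nuclear	CI	NDUFAB1	0
SDHA	SDHA	nuclear	CII	SDH	0
SDHB	SDHB	nuclear	CII	SDH	0
SDHC	SDHC	nuclear	CII	SDH	0
SDHD	SDHD	nuclear	CII	SDH	0
MT-CYB	MT-CYB	mitochondrial	CIII	subcomplex 1	0
UQCRQ	UQCRQ	nuclear	CIII	subcomplex 1	0
UQCRB	UQCRB	nuclear	CIII	subcomplex 1	0
UQCRC1	UQCRC1	nuclear	CIII	subcomplex 1	1
UQCRC2	UQCRC2	nuclear	CIII	subcomplex 1	1
CYC1	CYC1	nuclear	CIII	subcomplex 2	0
UQCRH	UQCRH	nuclear	CIII	subcomplex 2	0
UQCR10	UQCR10	nuclear	CIII	subcomplex 2	0
UQCR11	UQCR11	nuclear	CIII	subcomplex 2	1
UQCRFS1	UQCRFS1	nuclear	CIII	subcomplex 3	0
UQCRFS1-N	UQCRFS1	nuclear	CIII	subcomplex 3	1
MT-CO1	MT-CO1	mitochondrial	CIV	subcomplex 2	0
MT-CO2	MT-CO2	mitochondrial	CIV	subcomplex 2	0
MT-CO3	MT-CO3	mitochondrial	CIV	subcomplex 2	0
COX4I1	COX4I1	nuclear	CIV	subcomplex 1	0
COX4I2	COX4I2	nuclear	CIV	subcomplex 1	1
COX5A	COX5A	nuclear	CIV	subcomplex 1	0
COX5B	COX5B	nuclear	CIV	subcomplex 2	0
COX6A1	COX6A1	nuclear	CIV	subcomplex 2	1
COX6A2	COX6A2	nuclear	CIV	subcomplex 2	1
COX6B1	COX6B1	nuclear	CIV	subcomplex 2	1
COX6B2	COX6B2	nuclear	CIV	subcomplex 2	1
COX6C	COX6C	nuclear	CIV	subcomplex 2	0
COX7A1	COX7A1	nuclear	CIV	subcomplex 2	1
COX7A2	COX7A2	nuclear	CIV	subcomplex 2	1
COX7A2L	COX7A2L	nuclear	CIV	subcomplex 2	1
COX7B	COX7B	nuclear	CIV	subcomplex 2	1
COX7B2	COX7B2	nuclear	CIV	subcomplex 2	1
COX7C	COX7C	nuclear	CIV	subcomplex 2	0
COX8A	COX8A	nuclear	CIV	subcomplex 2	0
COX8C	COX8C	nuclear	CIV	subcomplex 2	1
NDUFA4L2	NDUFA4L2	nuclear	CIV	subcomplex 2	1
ATP5F1A	ATP5F1A	nuclear	CV	step 1	0
ATP5F1B	ATP5F1B	nuclear	CV	step 1	0
ATP5F1C	ATP5F1C	nuclear	CV	step 1	0
ATP5F1D	ATP5F1D	nuclear	CV	step 1	0
ATP5F1E	ATP5F1E	nuclear	CV	step 1	0
ATP5PB	ATP5PB	nuclear	CV	step 2	0
ATP5MC1	ATP5MC1	nuclear	CV	step 2	0
ATP5MC2	ATP5MC2	nuclear	CV	step 2	0
ATP5MC3	ATP5MC3	nuclear	CV	step 2	0
ATP5PD	ATP5PD	nuclear	CV	step 2	0
ATP5PF	ATP5PF	nuclear	CV	step 2	0
ATP5PO	ATP5PO	nuclear	CV	step 2	0
ATP5ME	ATP5ME	nuclear	CV	step 2	1
ATP5MF	ATP5MF	nuclear	CV	step 2	1
ATP5MG	ATP5MG	nuclear	CV	step 2	1
MT-ATP6	MT-ATP6	mitochondrial	CV	step 3	0
MT-ATP8	MT-ATP8	mitochondrial	CV	step 3	0
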