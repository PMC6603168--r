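gene	segment	region	start	end
IGHV1-2*01	V	GENE	0	288
IGHV1-2*01	V	FWR1	0	75
IGHV1-2*01	V	CDR1	75	99
IGHV1-2*01	V	FWR2	99	150
IGHV1-2*01	V	CDR2	150	174
IGHV1-2*01	V	FWR3	174	288
IGHV1-2*01	V	CYS	279	282
IGHV1-2*01	V	KABAT12	33	36
IGHV1-69*01	V	GENE	0	288
IGHV1-69*01	V	FWR1	0	75
IGHV1-69*01	V	CDR1	75	99
IGHV1-69*01	V	FWR2	99	150
IGHV1-69*01	V	CDR2	150	174
IGHV1-69*01	V	FWR3	174	288
IGHV1-69*01	V	CYS	279	282
IGHV1-69*01	V	KABAT12	33	36
IGHV3-23*01	V	GENE	0	288
IGHV3-23*01	V	FWR1	0	75
IGHV3-23*01	V	CDR1	75	99
IGHV3-23*01	V	FWR2	99	150
IGHV3-23*01	V	CDR2	150	174
IGHV3-23*01	V	FWR3	174	288
IGHV3-23*01	V	CYS	279	282
IGHV3-23*01	V	KABAT12	33	36
IGHV3-30*01	V	GENE	0	288
IGHV3-30*01	V	FWR1	0	75
IGHV3-30*01	V	CDR1	75	99
IGHV3-30*01	V	FWR2	99	150
IGHV3-30*01	V	CDR2	150	174
IGHV3-30*01	V	FWR3	174	288
IGHV3-30*01	V	CYS	279	282
IGHV3-30*01	V	KABAT12	33	36
IGHV3-33*01	V	GENE	0	288
IGHV3-33*01	V	FWR1	0	75
IGHV3-33*01	V	CDR1	75	99
IGHV3-33*01	V	FWR2	99	150
IGHV3-33*01	V	CDR2	150	174
IGHV3-33*01	V	FWR3	174	288
IGHV3-33*01	V	CYS	279	282
IGHV3-33*01	V	KABAT12	33	36
IGHV4-39*01	V	GENE	0	288
IGHV4-39*01	V	FWR1	0	75
IGHV4-39*01	V	CDR1	75	99
IGHV4-39*01	V	FWR2	99	150
IGHV4-39*01	V	CDR2	150	174
IGHV4-39*01	V	FWR3	174	288
IGHV4-39*01	V	CYS	279	282
IGHV4-39*01	V	KABAT12	33	36
IGHV4-59*01	V	GENE	0	288
IGHV4-59*01	V	FWR1	0	75
IGHV4-59*01	V	CDR1	75	99
IGHV4-59*01	V	FWR2	99	150
IGHV4-59*01	V	CDR2	150	174
IGHV4-59*01	V	FWR3	174	288
IGHV4-59*01	V	CYS	279	282
IGHV4-59*01	V	KABAT12	33	36
IGHV5-51*01	V	GENE	0	288
IGHV5-51*01	V	FWR1	0	75
IGHV5-51*01	V	CDR1	75	99
IGHV5-51*01	V	FWR2	99	150
IGHV5-51*01	V	CDR2	150	174
IGHV5-51*01	V	FWR3	174	288
IGHV5-51*01	V	CYS	279	282
IGHV5-51*01	V	KABAT12	33	36
IGHD2-2*01	D	GENE	0	16
IGHD3-10*01	D	GENE	0	16
IGHD4-17*01	D	GENE	0	16
IGHD6-19*01	D	GENE	0	16
IGHJ1*01	J	GENE	0	48
IGHJ1*01	J	JWF	9	12
IGHJ1*01	J	FWR4	12	48
IGHJ1*01	J	KABAT136	36	39
IGHJ2*01	J	GENE	0	48
IGHJ2*01	J	JWF	9	12
IGHJ2*01	J	FWR4	12	48
IGHJ2*01	J	KABAT136	36	39
IGHJ3*01	J	GENE	0	48
IGHJ3*01	J	JWF	9	12
IGHJ3*01	J	FWR4	12	48
IGHJ3*01	J	KABAT136	36	39
IGHJ4*01	J	GENE	0	48
IGHJ4*01	J	JWF	9	12
IGHJ4*01	J	FWR4	12	48
IGHJ4*01	J	KABAT136	36	39
IGHJ5*01	J	GENE	0	48
IGHJ5*01	J	JWF	9	12
IGHJ5*01	J	FWR4	12	48
IGHJ5*01	J	KABAT136	36	39
IGHJ6*01	J	GENE	0	48
IGHJ6*01	J	JWF	9	12
IGHJ6*01	J	FWR4	12	48
IGHJ6*01	J	KABAT136	36	39
IGHM	C	GENE	0	40
IGHG1	C	GENE	0	40
IGHG2	C	GENE	0	40
IGHG3	C	GENE	0	40
IGHG4	C	GENE	0	40
IGHA1	C	GENE	0	40
IGHA2	C	GENE	0	40
LEADER	L	GENE	0	18
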