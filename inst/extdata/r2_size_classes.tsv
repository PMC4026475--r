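taxon	individual	size_class	length	N	structure
East	FGB008	S1	220	20	(A)4(B)1(A)5(B)2(A)6(B)2
East	FGB008	S2	220	20	(A)4(B)1(A)5(B)2(A)7(B)1
East	ZY03	S1	209	19	(A)1(B)1(A)5(B)2(A)3(B)1(A)3(B)3
East	ZY03	S2	198	18	(A)1(B)1(A)5(B)2(A)2(B)1(A)3(B)3
East	ZY03	S3	187	17	(A)1(B)1(A)4(B)2(A)2(B)1(A)3(B)3
East	ZY03	S4	187	17	(A)1(B)1(A)5(B)1(A)2(B)1(A)3(B)3
East	YH05	S1	187	17	(A)10(B)7
East	HS04	S1	176	16	(A)2(B)7(A)3(B)4
East	HS04	S2	154	14	(A)2(B)2(A)2(B)2(A)1(B)5
East	HS04	S3	143	13	(A)2(B)4(A)3(B)4
East	LLJ028	S1	209	19	(C)1(D)6(C)1(D)4(C)5(D)1(C)1(D)1(C)1
East	LLJ028	S2	198	18	(C)2(D)4(C)1(D)4(C)5(D)1(C)1(D)1(C)1
East	WLB007	S1	209	19	(D)1(C)1(D)1(C)1(D)4(C)2(D)1(C)3(D)3(C)2
East	WLB007	S2	209	19	(D)1(C)1(D)1(C)1(D)3(C)3(D)1(C)3(D)3(C)2
East	ASY20	S1	209	19	(E)2(D)1(E)3(D)1(E)3(D)1(E)1(D)1(E)1(C)1(D)1(C)4(D)1(C)2
East	ASY20	S2	198	18	(E)1(D)1(E)1(D)5(E)1(C)1(D)1(C)4(D)1(C)2
East	ASY20	S3	176	16	(E)1(D)5(E)1(C)1(D)1(C)4(D)1(C)2
East	ASY20	S4	165	15	(E)1(D)1(E)1(D)4(E)1(C)1(D)1(C)2(D)1(C)2
Hainan	YGL418	S1	214	19	(C)1AACGC(D)6(C)1(D)1(C)3(D)2(C)1(D)1(C)3
Hainan	YGL418	S2	203	18	(C)1AACGC(D)5(C)1(D)1(C)3(D)2(C)1(D)1(C)3
Hainan	YGL418	S3	181	16	(C)1AACGC(D)4(C)1(D)1(C)3(D)1(C)1(D)1(C)3
Hainan	YG24	S1	209	19	(C)3(D)3(C)1(D)1(C)1(D)1(C)1(D)3(C)1(D)1(C)1(D)1(C)1
Hainan	YG11	S1	176	16	(C)5(D)1(C)4(D)1(C)1(D)1(C)1(D)1(C)1
Hainan	YG11	S2	154	14	(C)3(D)1(C)4(D)1(C)1(D)1(C)1(D)1(C)1
Hainan	CX03	S1	198	18	(C)7(D)3(C)4(D)1(C)3
Hainan	CX03	S2	187	17	(C)6(D)3(C)4(D)1(C)3
Central	TL07	S1	209	19	(C)19
Central	TL07	S2	176	16	(C)16
Central	JJ09	S1	198	18	(C)18
Central	JJ08	S1	77	7	(C)7
septentrionalis	SHC009	S1	209	19	(C)10(D)1(C)8
septentrionalis	SHC009	S2	187	17	(C)17
septentrionalis	WM32	S1	209	19	(C)19
septentrionalis	WM32	S2	198	18	(C)18
septentrionalis	YBG15	S1	165	15	(C)15
septentrionalis	YBG15	S2	33	3	(C)3
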