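# The 34 MSH6 missense variant carriers with evidence-based pathogenicity
# labels: 15 "likely Lynch syndrome" (LLS, pathogenic) and 19 "unlikely
# Lynch syndrome" (ULS, non-pathogenic), with the clinical and molecular
# evidence behind each label and the published criteria ("definition"
# column) that fired.
#
# dataset: "test" = carriers with biochemical functional assay data,
# "training" = carriers without (used to fit the model coefficients).
# minor_allele_frequency encodes the published polymorphism column:
# 0.01 = "a frequency of at least 0.01", 0.005 = a representative value for
# "below 0.01", "." = not available. FH / PTF / control columns encode the
# published Normal -> no, Abnormal -> yes (criterion met) convention.
#
# provenance: T<table>r<row>. Emendations vs the printed tables:
#   T4r19 (K728T): MSH6 IHC printed "Abnormal" contradicts the printed
#     definition "2,3" and the running text ("normal staining pattern in
#     IHC"); encoded normal.
#   T5r24: printed "S65L"; the running text prints S56L; encoded S56L.
#   T4r17: printed "S1441"; decoded as S144I per the running text.
variant	label	criteria	dataset	ihc_mlh1	ihc_msh2	ihc_msh6	msi	assay_mmr_activity	assay_msh2_interaction	assay_localization	assay_atp_hydrolysis	assay_mismatch_recognition	segregation_supportive	family_history_met	proband_tumor_met	control_freq_zero_n100	minor_allele_frequency	provenance
G566R	LLS	1	test	nd	nd	nd	H	inconclusive	normal	nd	abnormal	nd	nd	nd	nd	nd	.	T2r1
R976H	LLS	1,2	test	normal	normal	abnormal	H	nd	normal	nd	nd	abnormal	nd	nd	nd	nd	.	T2r2
G1139S	LLS	1,2	test	normal	inconclusive	abnormal	H	nd	nd	nd	abnormal	nd	nd	nd	nd	nd	.	T2r3
S1188N	LLS	1,2	test	normal	normal	abnormal	H	abnormal	nd	nd	nd	nd	nd	nd	nd	nd	.	T2r4
E1193K	LLS	1,2	test	normal	inconclusive	abnormal	H	abnormal	abnormal	nd	nd	nd	nd	nd	nd	nd	.	T2r5
L449P	LLS	2,3	training	normal	normal	abnormal	H	nd	nd	nd	nd	nd	nd	yes	yes	nd	.	T3r6
C559Y	LLS	3	training	nd	nd	nd	nd	nd	nd	nd	nd	nd	yes	yes	yes	nd	.	T3r7
P591S	LLS	2,3	training	normal	normal	abnormal	H	nd	nd	nd	nd	nd	nd	yes	yes	yes	.	T3r8
P623L	LLS	3	training	normal	normal	abnormal	L	nd	nd	nd	nd	nd	nd	no	yes	yes	.	T3r9
G670R	LLS	2	training	normal	normal	abnormal	H	nd	nd	nd	nd	nd	nd	no	no	nd	.	T3r10
R772W	LLS	2	training	normal	normal	abnormal	H	nd	nd	nd	nd	nd	nd	no	no	inconclusive	.	T3r11
Y969C	LLS	2,3	training	normal	normal	abnormal	H	nd	nd	nd	nd	nd	yes	yes	yes	inconclusive	.	T3r12
G1069E	LLS	2	training	normal	normal	abnormal	H	nd	nd	nd	nd	nd	nd	no	no	nd	.	T3r13
R1076C	LLS	3	training	normal	normal	abnormal	nd	nd	nd	nd	nd	nd	nd	yes	yes	nd	.	T3r14
A1236P	LLS	2,3	training	normal	normal	abnormal	H	nd	nd	nd	nd	nd	nd	yes	nd	yes	.	T3r15
R128L	ULS	2	test	abnormal	normal	normal	H	normal	normal	nd	nd	nd	nd	nd	nd	nd	.	T4r16
S144I	ULS	2,3	test	normal	normal	normal	S	normal	normal	nd	nd	nd	nd	nd	nd	nd	0.005	T4r17
L396V	ULS	1,2	test	normal	normal	normal	H	normal	nd	nd	nd	nd	nd	nd	nd	nd	0.01	T4r18
K728T	ULS	2,3	test	abnormal	abnormal	normal	S	normal	normal	nd	nd	nd	nd	nd	nd	nd	.	T4r19
K13T	ULS	3	training	normal	normal	normal	S	nd	nd	nd	nd	nd	nd	nd	nd	nd	0.005	T5r20
A25V	ULS	1	training	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	0.01	T5r21
G39E	ULS	1	training	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	0.01	T5r22
G54A	ULS	3	training	normal	normal	normal	S	nd	nd	nd	nd	nd	nd	nd	nd	nd	.	T5r23
S56L	ULS	3	training	normal	normal	normal	S	nd	nd	nd	nd	nd	nd	nd	nd	nd	0.005	T5r24
C196F	ULS	1	training	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	0.01	T5r25
R468H	ULS	3	training	normal	normal	normal	S	nd	nd	nd	nd	nd	nd	nd	nd	nd	0.005	T5r26
S503C	ULS	3	training	normal	normal	normal	S	nd	nd	nd	nd	nd	nd	nd	nd	nd	0.005	T5r27
R635G	ULS	3	training	normal	normal	normal	S	nd	nd	nd	nd	nd	nd	nd	nd	nd	.	T5r28
I886V	ULS	1	training	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	0.01	T5r29
I1054F	ULS	3	training	normal	normal	normal	S	nd	nd	nd	nd	nd	nd	nd	nd	nd	.	T5r30
E1163V	ULS	1	training	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	0.01	T5r31
E1196K	ULS	1	training	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	0.01	T5r32
E1234Q	ULS	1	training	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	0.01	T5r33
E1304K	ULS	1	training	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	nd	0.01	T5r34
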