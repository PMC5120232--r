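rank	feature_id	category	mi_value	name
1	hsa05211	KEGG	0.011	Renal cell carcinoma
2	GO:0007265	GO	0.011	Ras protein signal transduction
3	hsa04010	KEGG	0.011	MAPK signaling pathway
4	hsa05212	KEGG	0.011	Pancreatic cancer
5	hsa05200	KEGG	0.011	Pathways in cancer
6	hsa05210	KEGG	0.011	Colorectal cancer
7	hsa05214	KEGG	0.011	Glioma
8	hsa05220	KEGG	0.011	Chronic myeloid leukemia
9	hsa05223	KEGG	0.01	Non-small-cell lung cancer
10	hsa04510	KEGG	0.01	Focal adhesion
11	hsa05213	KEGG	0.01	Endometrial cancer
12	hsa05221	KEGG	0.01	Acute myeloid leukemia
13	hsa05215	KEGG	0.01	Prostate cancer
14	hsa05160	KEGG	0.01	Hepatitis C
15	GO:0048011	GO	0.01	Neurotrophin-TRK receptor signaling pathway
16	hsa04012	KEGG	0.01	ErbB signaling pathway
17	GO:0016772	GO	0.01	Transferase activity, transferring phosphorus-containing groups
18	hsa04660	KEGG	0.01	T cell receptor signaling pathway
19	GO:0016303	GO	0.01	1-Phosphatidylinositol-3-kinase activity
20	hsa04150	KEGG	0.01	mTOR signaling pathway
21	GO:0004713	GO	0.01	Protein tyrosine kinase activity
22	hsa04722	KEGG	0.01	Neurotrophin signaling pathway
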