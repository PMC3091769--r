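# Example cluster definition file for cluster_delta_summary():
# tab-delimited, one gene per row, grouped by cluster label.
# These are well-known myeloid genomic gene clusters (chemokine clusters
# on 17q11.2 and 16q13, the CD1, C1Q, SLAM-family, CD300 and IFITM
# clusters) given as a format illustration; when analyzing your own
# data the gene_id column must match your annotation's gene ids.
cluster	gene_id
CCL_17q11.2	CCL2
CCL_17q11.2	CCL3
CCL_17q11.2	CCL13
CCL_17q11.2	CCL23
CCL_16q13	CCL17
CCL_16q13	CX3CL1
CCL_16q13	CCL22
CD1	CD1A
CD1	CD1B
CD1	CD1C
CD1	CD1D
CD1	CD1E
C1Q	C1QA
C1Q	C1QB
C1Q	C1QC
CD300	CD300A
CD300	CD300C
CD300	CD300LB
IFITM	IFITM1
IFITM	IFITM2
IFITM	IFITM3
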