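locus	snp_id	cpg_id	outcome	panel	beta_exposure	se_exposure	beta_outcome	se_outcome	source
ADIPOQ	rs266772	cg05578595	adiponectin	trait	0.982	0.103	-0.629	0.143	UK10K Consortium (TwinsUK)
ABO	rs687621	cg21160290	IL-6	trait	0.912	0.036	-0.245	0.026	Naitza et al.
LEPR	rs2211651	cg04111102	CRP	trait	0.682	0.036	-0.170	0.022	Reiner et al.
APOB	rs541041	cg25035485	ApoB	trait	0.627	0.053	0.098	0.013	Kettunen et al.
ADIPOQ	rs169109	cg05578595	adiponectin	trait	0.383	0.036	-0.052	0.005	Dastani et al.
SORT1	rs7528419	cg00908766	ApoB	trait	-0.980	0.037	-0.089	0.012	Kettunen et al.
APOA1	rs625145	cg04087571	ApoA1	trait	-0.884	0.044	0.057	0.013	Kettunen et al.
FADS1	rs174544	cg19610905	total_cholesterol	trait	-0.655	0.031	0.047	0.004	Willer et al.
ADCY3	rs6749422	cg01884057	BMI	trait	0.908	0.026	0.068	0.007	Felix et al.
ABO	rs116552240	cg21160290	expression_adipose	eqtl	0.912	0.036	0.548	0.069	GTEx adipose
ADCY3	rs6737082	cg01884057	expression_adipose	eqtl	0.908	0.026	0.208	0.047	GTEx adipose
ADIPOQ	rs266772	cg05578595	expression_adipose	eqtl	0.982	0.103	-0.339	0.078	GTEx adipose
APOA1	rs688456	cg04087571	expression_heart	eqtl	-0.884	0.044	0.420	0.095	GTEx heart
APOB	rs541041	cg25035485	expression_heart	eqtl	-0.627	0.053	-0.370	0.066	GTEx heart
SORT1	rs646776	cg00908766	expression_liver	eqtl	-0.980	0.037	-1.240	0.105	GTEx liver
FADS1	rs174559	cg19610905	expression_pancreas	eqtl	-0.655	0.031	-0.707	0.089	GTEx pancreas
IL6R	rs10908837	cg02856953	expression_blood	eqtl	-0.303	0.039	-0.120	0.020	GTEx whole blood
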