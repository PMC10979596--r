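substrate_name	smiles	ec_number	organism	uniprot_id	sequence	enzyme_type	mutation_spec	km_value
ethanol	OCC	1.1.1.1	Synthetica exempli		MKTAYIAKQRQISFVKSHFSRQLE	wildtype		2
ethanol	CCO	1.1.1.1	Synthetica exempli		MKTAYIAKQRQISFVKSHFSRQLE	wildtype		5
acetate	CC(=O)O	2.7.1.1	Synthetica exempli		MNIFEMLRIDEGLRLKIYKDTEGY	wildtype		1
acetate	CC(=O)O	2.7.1.1	Synthetica exempli		MNIFEMLRIDEGLRLKIYKDTEGY	wildtype		0.5
ethanol	CCO	3.1.1.1	Synthetica exempli		AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA	wildtype		1
ethanol	CCO	1.1.1.2	Synthetica exempli		MADEEKLPPGWEKRMSRSSGRVYY	wildtype		0
mystery	notasmiles	2.1.1.1	Synthetica exempli		MTEYKLVVVGAGGVGKSALTIQLI	wildtype		1
benzene	c1ccccc1	3.2.1.1	Synthetica exempli		MKVLWAALLVTFLAGCQAKVEQAV	wildtype		0.8
lactate	CC(O)C(=O)O	4.1.1.1	Synthetica exempli		MGLSAEQKAIVRETWALVKPDLPA	mutant	A5G	1.2
glycine	NCC(=O)O	5.3.1.1	Synthetica exempli		MVLSPADKTNVKAAWGKVGAHAGE	wildtype		0.9
pyruvate	CC(=O)C(=O)O	6.3.1.1	Synthetica exempli		MPKIIEAIYENGVFKPLQKVDLKE	mutant	K3R	3.5
phenol	Oc1ccccc1	2.3.1.1	Synthetica exempli		MSTNPKPQRKTKRNTNRRPQDVKF	wildtype		0.25
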