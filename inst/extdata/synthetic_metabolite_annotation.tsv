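metabolite_id	compartment	compound_key	super_pathway
fmet_001	faecal	CK0001	amino acid
fmet_002	faecal	CK0002	lipid
fmet_003	faecal	CK0003	amino acid
fmet_004	faecal	CK0004	amino acid
fmet_005	faecal	CK0005	carbohydrate
fmet_006	faecal	CK0006	energy
fmet_007	faecal	CK0007	carbohydrate
fmet_008	faecal	CK0008	carbohydrate
fmet_009	faecal	CK0009	amino acid
fmet_010	faecal	CK0010	xenobiotics
fmet_011	faecal	CK0011	peptide
fmet_012	faecal	CK0012	xenobiotics
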