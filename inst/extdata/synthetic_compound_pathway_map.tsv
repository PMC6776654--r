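compound_key	pathway_id
CK0001	pwy_001
CK0001	pwy_002
CK0002	pwy_001
CK0003	pwy_003
CK0005	pwy_001
CK0005	pwy_002
CK0005	pwy_004
CK0007	pwy_002
CK0008	pwy_005
CK0008	pwy_003
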