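snp_id	risk_allele	weight
rs1001	A	1
rs1002	A	1
rs1003	A	1
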