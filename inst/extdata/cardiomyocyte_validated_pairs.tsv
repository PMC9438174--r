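mirna_id	gene_id	confidence	source	profile
hsa-miR-124-3p	EPM2AIP1	high	curated	profile1
hsa-miR-512-3p	LBH	high	curated	profile1
hsa-miR-302d-3p	CASQ2	high	curated	profile2
hsa-miR-1323	EPM2AIP1	high	curated	profile1
hsa-miR-532-5p	MICB	high	curated	profile1
hsa-miR-526b-5p	EPM2AIP1	high	curated	profile1
hsa-miR-30a-5p	TSPAN33	high	curated	profile2
hsa-miR-302c-3p	CASQ2	high	curated	profile2
hsa-miR-519a-3p	LBH	high	curated	profile1
hsa-miR-520g-3p	EPM2AIP1	high	curated	profile1
hsa-miR-519a-3p	CRIP2	high	curated	profile1
hsa-miR-30a-5p	MICB	high	curated	profile1
hsa-miR-520g-3p	LBH	high	curated	profile1
hsa-miR-525-5p	CRIP2	high	curated	profile1
hsa-let-7g-5p	FGFR3	high	curated	profile1
hsa-miR-30a-5p	TMEM30B	high	curated	profile2
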