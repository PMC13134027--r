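subtype	n	edema	mass_effect	seizure	icp	exophthalmos	subcutaneous_mass	incidental
POM	6	0	0	0	1	0	3	2
SOM_I	37	2	1	0	1	14	5	16
SOM_IIA	57	14	8	6	4	11	8	23
SOM_IIB	68	49	35	15	21	5	0	17
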