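variant_class	category	n
SNP	transition	385336
SNP	transversion	241170
InDel	all	89173
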