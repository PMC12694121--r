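Chrom	Start	End	Length (bp)
5A	673837810	674334747	496938
5A	680382639	682026829	1644191
5A	682106425	682770497	664073
5A	691500001	695000001	3500001
5A	700302103	701184634	882532
5A	709603814	709631542	27729
5A	712000001	713264094	1264094
7B	714825625	715608889	783265
7B	717391811	717688886	297076
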