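Chrom	Start	End	Length (bp)
5A	673837810	674334747	496938
5A	680382639	682026829	1644191
5A	682106425	682770497	664073
5A	691443224	696644520	5201297
5A	700302103	701184634	882532
5A	709603814	709631542	27729
5A	711943509	713264094	1320586
7B	714825625	715608889	783265
7B	717391811	717688886	297076
7B	727435274	727441287	6014
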