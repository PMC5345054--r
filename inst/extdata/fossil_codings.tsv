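Scelianoma_compacta	0020001000000000-1000000010000000110000000000--0??00000002000100010000--0-000000--1--000???????????????????????????????????????????????????????
Tropirhinus_palpebratus	002000101000000100000010000000000000000000000--0??00000002000000001000--0-00000000???000???????????????????????????????????????????????????????
Diaprepes_anticus	002000100000010110000000000120000000000000001--0??00000002000000000000--0-000000--000100???????????????????????????????????????????????????????
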