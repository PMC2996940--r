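>F0011_A1_t1
YQVLMCDSSKVCQSNHRSMMMFSANWEEDYWKFHINLASRENTEIKNCQDLDARTCCLSNKQQQVIFYWTTDVMTNDMETLCHNWWRWKYMWCWLMMAEVSYHFNHMVENANGKAVCWMQ
>F0011_A2_t1
YQVLMCDSSKVCGSNHRSMMMFSANWETKYWKFHIYLASRENTEIKNCQDQDARTCCMSNKQQQSIFSWTTDEAKNDMETLCHTWWRWKPMWCWLMTAEVSYHFNAVVENANGKAVCWMQ
>F0011_B1_t1
WQVLLCDVYKVCWSNHRSMMMFSQNHEPDYWKNHHYKASDAATEIKNCQYLDARTCCHHNFRQQVIFYWTTDEMTKDMETNCHTWWRWKYMWCGKMTAEVCYDFNHKVENANGNAVCWMQ
>F0011_B2_t1
WQVLLCDYYKVNWSNLRSMMMFSQNHEPDYWKNHHYKASRAATEIKNCQYLDARTCCHHNFRQQVIFYWTTDEMTRDMETLCHTWWRWKYMWCGKMTAEVCTDFNHKVENANGNADCWMG
>F0011_OA_t1
NQVLMVDSSCVLEVNLLSHMMFWETWELDYWKNHQYLASRRNQPNENRMYNDARTDRQWNFQQQVIWYYAMDEMTKDMEDWCIYWWRWMNSWCGRNNAEVCTDFNHVVKHANVKAVCWMQ
>F0011_OB_t1
NQVLMVWHSMVCSVNHNYMMMFWENWIGDYWKNHHYLASERNSEIKYLQYNDAFTDRKWNFQSQVIVYYATDEMTDDMETWEHTWWRWMNMWFGRNHAEVCYNFNHVVKMFNVKAVCWMQ
>F0011_A1_t2
YQVLMCDSSKVCQSNHRSMMMFSANWEEDYWKFHINLASRENTEIKNCQDLDARTCCLSNKQQQVIFYWTTDVMTNDMETLCHNWWRWKYMWCWLM------------------------
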