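>F0007_A1_t1
MYNHMGTDFMNPRDDAFDKIPCGTEVCMVDAQRTPNMMNMWHGPNRANLHIGLAQVVLRLCDFGESGENVKEFIEFHGPTMPCRNDGVIGIAWERMHAIMTRALLTMVMMNHHDANREEH
>F0007_B1_t1
MKNHMGTEFMNLRLEAIDKIPCTTEVPMVDAQRTPNMGNMWHGPNRANLRELLALVVWPLCAFGESSETWQEFIEFSKPTCGCRSDRVDIIGWERIHAIMTRACLTMVCHNHHDVNREEH
>F0007_OA_t1
MHDHFPTRHMLCRDEQFGKIPCGTENPMVGAPRHANMGGNWHGPHRANLHKYSMLEELPLCAFGESEETWKEQIPFSGKPYVCRGYQVEHIGWELFNESMWYFTLTMRMMNVHVWNREEH
>F0007_OB_t1
MKDHFRTEHMICIDETFGKIPCGTYNPMVGAPRHALMEEDWHGAHRANLLIYSALPELILSFFGESEETAKYQKPFMGKTYGVKSYRVMWIGWELFNEIMTYSTLKMRMMNQHDWNRELH
>F0007_B1_t2
MKNHMGTEFMNLRLEAIDKIPCTTEVPMVDAQRTPNMGNMWHGPNRANLRELLALVVWPLCAFGESSETWQEFIEFSKPTCGCRSDRVDIIGWERI------------------------
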