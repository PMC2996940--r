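>F0013_A1_t1
RSVFGKPSASTCIERCDIVWCERCSEDDEAKLSIPCHCWLGHGFWGHRRHDTILKCKTINWAEITLKIACQPFAAIMNMPFSNFECKCIDSKVTGCFMVHTAGHHAGWYRLKTHNYFYWL
>F0013_B1_t1
RSVFGKPSAQQCIERCPIHKCERCSEYDEQKISIPCHCWLHEFFKGHRNHKTILKCKVYNWAEITMKIACSYFAAIYNVPFSNFEVWCIFSKVWLGFMVHTGGNWHGWYCLKTYNEFYWL
>F0013_B2_t1
RSVFGKPSAAQCIDRCPIHKCERCSEDDEQKISIPCHCWLHESFKGHRRHATILKCKPYNWAEITMKIACSYFAFIYNVPFSNFKCWCIDSKLWLGFMVHTGGLWHGWARLKTYNYFYWL
>F0013_OA_t1
NSVVGKHCQYNFINRIDIHNHDMCDEDDELKISDPKHCWLTEGFAGHAVHRPILSTATIMWAEDRMKIVCQMFAAKRNRPCSLFECKCIYSEMWFCRVVHTKKHHHAWYRKEEHDYFYWQ
>F0013_OB_t1
QSVFFEPCQYNCILRIDIHWQDICSEDDELKISIPKHCWLHEGYAGHAVDFTILDTWTIMWAEIRMSIMCQMFAAKRNNPCHNFECKCAYSKMDFCQVVATEKHHHAWNRLEEHDGAYWQ
>F0013_OB_t2
QSVFFEPCQYNCILRIDIHWQDICSEDDELKISIPKHCWLHEGYAGHAVDFTILDTWTIMWAEIRMSIMCQMFAAKRNNPCHNFECKCAYSKMDFC------------------------
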