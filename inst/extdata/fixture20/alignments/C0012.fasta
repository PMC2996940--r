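>F0012_A1_t1
GITNILCHMTCQEINGHFRGWQVWMWKFATNFMAADFSRQILGTVNESGYSQTQCYGMWNSDEPIEKPHVAVFFHRVCQYCCLSLSRGSHVPSDPASYCPEPPYGWDNIEQEQKSWQGGF
>F0012_A2_t1
GITNILCHMTCQEINGHFRVWDFWMYKFATNFMAADFSRQILGTVNESGKWQSQCWGMWNSDEPILKPHKEVRFHRVCQYQCLSLSRGSHVPSNPASYCPRPPYGWDNIEQEQKSWLGGF
>F0012_B1_t1
GIHNILCFMTPQLINGHFLPWDFWMYMFATWFMAATFRRTILGTVHEVGYSQSQCQGMWNVDEPIGPPIWCMCFHAVCQYWCHGLSRGMHVRSNPATYCPEPPYALDNIEQEQSSWCGGD
>F0012_OA_t1
GMTNILCFMTQQRINLHRRPWDFWMWKYASWHQAANFSIQILWTVHPVGYSQSIVRGPWNVDEPIYKPIVWVCFVPQCQMCCDSRIYYWHVYVNYASYCPEPPYAWDDCEQKWKSWCKMW
>F0012_OB_t1
GMTNIVCFMTVQRISPHFRPWDFWMWKYACWHQAHDFSRQILWTVHPVGASWSIVRGPWNVDEPIYKFIVWVCIVRVCIYCWDSRARTWHVFSNRASVCQEPPNAWDNCEQPWGSKCLKW
>F0012_B1_t2
GIHNILCFMTPQLINGHFLPWDFWMYMFATWFMAATFRRTILGTVHEVGYSQSQCQGMWNVDEPIGPPIWCMCFHAVCQYWCHGLSRGMHVRSNPA------------------------
>F0012_OB_t2
GMTNIVCFMTVQRISPHFRPWDFWMWKYACWHQAHDFSRQILWTVHPVGASWSIVRGPWNVDEPIYKFIVWVCIVRVCIYCWDSRARTWHVFSNRA------------------------
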