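>F0017_A1_t1
EFKPHYYNPHQRRCLEQCATRNNPWFEYYFDSTNVTDSIAFGKRFCLVMCYEGLSVVCQTDLEFMLYWIPQFLKWFFRPRPDNASEKRQNLRDQAIITTDCCSSKFYTAFWQIRHCQEHD
>F0017_A2_t1
EVQPHYYNPHQFRCLEQCATRNEPWFEMYWDSTNVTDSWAFGKRFCLVMCYEGLSVVCQKDYEFMLRWIPQFLTWFFRPRPCYASEKRQTLRDQAIITTYCCSSKFYTAFWQIRHCQETD
>F0017_B1_t1
MVQPHYYNPHQRFCLEQYATCNEPWFEMYFDSTNVTDSTVFGKRICLVMCGEGLSVVVQTDKEPMLWRIPKFLTWHFRPRTDYASVERRTLQEDPQACFPTCSPKFYTKKWQIRHCQPHI
>F0017_OA_t1
MGMGNPYNPHQFFCPEQCHQENPPWLELYFDSGNMMDSHASQKRICLVMCYLSRSVGTLTDYNFLYYRPRFQLVGFVRFAPDYASSKRQEVRKGPIYQTDECSSKHNSAVYRIRHCQESP
>F0017_OB_t1
MGQWNGYNPHQFFCMEICAVCNPPWFEMYFYIGNMMDSHHSQKRIFLVMCCLGRSVVTQTDYEWMFQRPPFFMTAFFRQAPDYASFKRQTLRKGPIYQTDHCSSKFITAYYRIRHCIEKP
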