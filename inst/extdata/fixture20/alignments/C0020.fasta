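>F0020_A1_t1
LGRSHTALPECLEHFFKCGHRRIDFGQDWDFFRLLAYIKNPPLYDFNAMAVIPCFNPNNGCKWHDGVLPWVSNNHGNMIMAACRQIHRKDTWHNVPDYPNIPCNMPNMTLGSENTRGNKI
>F0020_B1_t1
LNDSHPAPPECLVHFFKQGHQRCDFKQDDDFFRLGWDIKNWPLYDFNQMAVRAHNNPNNGCQDKFGVPPRVMNNHINFGSQACRGIHSEDTWDNVPNYPNIPCNMPNMTEGSENTRGTKI
>F0020_B2_t1
LNDSHPAPCECLEHFFKWGHQRCDFKQDDDFFRLGAHIKNPPLYDFNAMAVRACNNPNNGCQDHFGVPQRVMNNHINFGMQACRGRHSEDTWDNVPNLPNIPCNMPNMTEGSENTRGNKI
>F0020_OA_t1
LVDPHFAEWDPLEVNSKPGLKSCDFVQKDAFFAQMIDNTAWYLYCDGAMAFRKCFNPMNEGEWHDGVWPVVMVNNIGMHMSICYDIHREDHQHNVPNDCCIPCNDPRMHLGSENTYYNSI
>F0020_OB_t1
LVDGHFAEWEFLEHFFKPGLQTCDNVQDDAIAAQMIDIKMQYLADDAAMAVRKCFNPMNEVLWHDLVKPYVCVNHTNMHMQICEDIHREDHQHNMPDYPCIYCNMPRQHLGSENTYWCWI
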