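>F0006_A1_t1
TLSFLVHAQFWMYFATREHTSINKLSLATLMQQLGWPQQGLYSLIAGHGTITIGELWPSPMKEVYNGPDGIGDGRIEFTAYDMASKWKWWVEHAFDRNWAKCGRPGKPSPSDKKPSFQTH
>F0006_A2_t1
TLSFLVHAQFWMYPATREHTLINKLSLATLMWQLGDPQGGLYSLIAGTGTITIGVHWPSPASEVYNGPDGIGDGRIEFTARDMASKHKTWWEHAFDGNWARCNRPGKPSPFDKKPSFQTH
>F0006_B1_t1
TLAGLVHANFWMGPANCEHTLGTKLSLITLMQQNGDWQGGLLSLNLGTGTWAMGVLWQSPMSEVYNGADGIYDGRAEFGCIDQASPHKTWREHAFDPEWAKCGNPCKPSPMDKKPSFQKH
>F0006_B2_t1
ILAGPVHANFWMYPANCEHTLGNKLSLATLMQQNGDWQGGLLSLNLGTGSWAIGVLWQSPFSEVYNGHDGIYDGRAEFVCIDQASPHKTEWEHAADPEWAKCGNPCKPSPQDKKPSFQKH
>F0006_OA_t1
TLCFASHMKGARWLDYRESQLIIDLDRATKIQQASDWHGGLYAPCHDWGTWQGGVLIPSPMNECYNGEDVIMDGAPEDGMIDQAPPNGTWQSKSFVRNWAKCGQLGKPSPMDKKPSFQDI
>F0006_OB_t1
CLCFLVHMCGWEWGDYYESQLIIKTDLATFVQQAVYWQGGLFSPNADIGTWFGGVLWCHPMSEKYNGHEKIMDCRPEDTMIDQASLNQTWCSKSFVRNWAKLGRPWKPSPEAKQPSFQDW
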