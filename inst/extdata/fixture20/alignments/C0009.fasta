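>F0009_A1_t1
QWWQAKMFFVKFWDGGGERRCYRCLQDICIMYWRWDRDCVFNVGGGEEVCGNWCKANTEWAHKNLNYKTEFNNTYWTGNHRAVWFSIMRITFCYSTYAHRNYHRMTGRMLQPDEINAPAL
>F0009_B1_t1
KWRQLKMFFDKFWDEGGEWRDKCCLYNIFIMYWMKDRKCVFTVPSAECKCENWKWNTQEKPFKNCNYKTEFNNVHWTGNHRNRWFSIMSIGSCYSTYCHRHQFRDCGRRLQPDNICKLAL
>F0009_OA_t1
QYSKAKMFDVKFWDKGGEWHLKCCLQHIMIYYYPGDRPDVFIGGCWECKAQNWTWRTWYWPEPDCCYSTEFKNTYWLGNHRNVWFTIKRIGFSYSLYPREHTHRSPTMRLWPDNINKPLQ
>F0009_OB_t1
QWWKAAMFFPKFWDNGGEWHLKCCLQHIYIYYWPWDRDDVFIVGCWPCWAQHWTHRTWYSPIKNCQLMTEFNNTYWLGNHRNQWFDIKRIGFNYSTYPRRHTHRMDTRRLWPGNLNIVLQ
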