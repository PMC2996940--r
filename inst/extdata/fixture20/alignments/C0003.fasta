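>F0003_A1_t1
QRHVIKMTHMEVDCAMKWSMVFMLKVNHPSDRGYSVDMKFICFCHRDNEMHLCYYTISQQNCEGSDIWRIRSDQKTVSARLDCENVSHTHDFLHNHELCQTFRKLQPPQDGYNGEQAWYR
>F0003_B1_t1
FRHVIRMTHMTEDCAMKWSMVFMIWLNHPKDWGPSHKMHFICFNLCWNEMELCYYTIHQQNCEGPDISRGRSEQKTWSADLDYLNHFYNFDGLGNEEECCTIRDLQWPQDGYKGEQDWYR
>F0003_OA_t1
VRHVNRRTHNKIFCHHKWSMVFAWDQVHVWGWGPSEGMKTICNCGRANYVHDTYYTSNQQNGTGDDIWHGGSCQDTVSAETWCENESYWPDALGNHMECCTIRSLQPPQKTYKNENDKQR
>F0003_OB_t1
VRHVNDRTPMFRDCHPKWSMVNRWDLTHGEGWCPSVWIKGICNCGRVNEVHFCKYTSNQQNFTGDPIWRGGSEQDTVSARRWCENESYWPMALVNHQECCTLASLQPPQDGYKNEMDMQR
>F0003_B1_t2
FRHVIRMTHMTEDCAMKWSMVFMIWLNHPKDWGPSHKMHFICFNLCWNEMELCYYTIHQQNCEGPDISRGRSEQKTWSADLDYLNHFYNFDGLGNE------------------------
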