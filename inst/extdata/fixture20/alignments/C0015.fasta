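>F0015_A1_t1
ICNVVYHKMFIVYFEIENCASVRCPGVPSEEGEFSEEMFHAIATFFLCYSYLGQADARFYWPEIRNHSDVRHHYFMSNYAKRHGMFIRFEFFAHMVGGSGQFSDIVHRIHAGSYKSETPN
>F0015_B1_t1
ICNVCVRKMFEHYFPDENCAFGRPSFTESVEGEWQESMFHWHAVEFLCGKYYGHPDARFYWPAIYDPLDLNAHYFMSNYMDVHGQFIRFVFFAHMVLGSDDFPEIDHRIHGGSYLTEKPN
>F0015_OA_t1
ERNQCYHKMFIHYFVEEICEFVRCSVWPRTYGEFGETMFHARAVFFLCGSTHDHPDAGLYWPEMRDQWYKGKWYFMSLYMIVMGNTERCVFFEMMVWYSQRAPDMQHRIHGGECWTENPC
>F0015_OB_t1
IMNHCNHKMFIHYFVIEICWFVRCSVWPRTEGEQNETMFHAEAVFQLCGSYCDHPWAVLHMPEMRDQLDSGKHYFMSLYMVFMGNTIRCVYKEHTVGYSQQGPDMSHRIHGGSCDTENPC
>F0015_A1_t2
ICNVVYHKMFIVYFEIENCASVRCPGVPSEEGEFSEEMFHAIATFFLCYSYLGQADARFYWPEIRNHSDVRHHYFMSNYAKRHGMFIRFEFFAHMV------------------------
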