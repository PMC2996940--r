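>F0018_A1_t1
RPSILKFPQSLHSTLLKGNTIWQAERQSWIRKDYSMWSSQVFMWLDQQIGHVAICYGYKWPSTHMGAHLGPEMRGEMCQHPYCFFNCGKNCSTQNKFDSNTTDMTPFEDMEKMYHINNYE
>F0018_B1_t1
RMSILKFPQMLLTTLLHRNTLWQSGRCSCISKDYEMWSSQPHMWKDQQIGHVAIYYGHKEPCTHMLGHLGGEESGQQCQHPYCIFPCGKNQRTQNKFDSNYTTSTLFMIDHTMYHWNNYE
>F0018_B2_t1
RPSILKFPQMLLTTLLNRNTLWQSGRFICIRKDYEMWSSQPPMWKDQQIGHVAIPYGHKEPCTHMLGHLGPECSGQQCQHPYCIFPCGKNQRTLNKFDSNYTDSTLFMIDHTMYHWNCYE
>F0018_OA_t1
RRSSLKKYQMCMTTLLHPNTLWWSLGWGWIRSCYSSWSFGPMTWKAQQFGHLAMLYGYKMPTTHNWAHLIPYQRGQDGYHCYCIFKFPLNIRTQNKHFSDYTDISQFEDMQTMYFQNGYE
>F0018_OB_t1
RRSKLKWYQMLLTTLLHPNTLWWDIRFGWIRSDYSSWSFQFMTWKCQQTQHLGILYFYKMPCTHNWAHMIPVMRGQDCQHQYCIEACPANIRTQLKHPSNYTDITQFEGMWTMYFQNGYE
>F0018_A1_t2
RPSILKFPQSLHSTLLKGNTIWQAERQSWIRKDYSMWSSQVFMWLDQQIGHVAICYGYKWPSTHMGAHLGPEMRGEMCQHPYCFFNCGKNCSTQNK------------------------
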