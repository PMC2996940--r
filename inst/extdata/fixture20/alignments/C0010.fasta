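>F0010_A1_t1
YDSDLLQEAAFEQDIAWNADGRKMWMTECLLDNQFDMYKCVQINCCRQNKGSTWTHDCVMRRQHPLGACAFQCVHFPRWGAIQTHIYYIDIQVAKWPMVNCNFGWYVEIMHPNPVLLLYD
>F0010_A2_t1
YDSDLLQEAAFEQDIAWNASGVKMWMTECKLDNQFDMYRCVQINDCRQNKGSTWTHDCGMRRDQQLGACAFQCVHFPYTGAGQTHPYYIDAQVAPWQMVNCNFGLYVSIMHPNPVLHLYQ
>F0010_B1_t1
YDSDLLQEARVEVDTAHHASGEDMAMTECILDSIFDMFFCVQINDCRCPKGSTWTMDCGMRRDQDLGACHFQCVHFPYGEMGQWYWYCIDAQIAPWPMVSPNFGLYVSIMHPNPDCCLYQ
>F0010_OA_t1
YDSTLMQEARDHSYIRYHDDGEKRPFSECLVDFIFSMSQCRQLNPCRQIKCITWQMPCGHRRDQDLGAVHFQSTPFPNWEWGVWPHPWFDAQIAPWGMKNPNFCLYVSIVDPHMDCCLYR
>F0010_OB_t1
YDSTWMGEAYDMSYIQYADDGNKRADTECLLDFIFDMSQTRQILPCRQIKYSTWTMPCWHWHDQDLGASHFQSVPFPNAEWGEWHRPWFIAQIAPWYMVNPNFGLEVSIMQPHMDCCLYQ
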