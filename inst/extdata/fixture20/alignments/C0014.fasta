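>F0014_A1_t1
FGFMTIWIHFHECGCVRLTINVPSDWCWVHCLTRFETWCDGAQHPNHGDMQFSSTTLVWKIYPSGRCIVDWGVWCYGANAQAPAICGSPMTTMFEQIVNGFCGRDIYATSYVDVHCNVMR
>F0014_B1_t1
FSFMTIWIFYPECQCVFLTIKHPPDWCWVHCLWVWAWWCLGAIHANCGHMQFSSTGFVHKIYPSGRAIAVWAVWFHYANACAPAIVGSPMTKKFEQIVNSYKERDIYITHYVDRHGNVSN
>F0014_B2_t1
FSFRTIWIFYPECKCVFLTIKHPPDWCWVHCLWVWAWWCLGAIHANCGDMQFSSTGFVDKIYPSGRAIAVWAVWFHGANACAPAIVGSPMTKKFEQIVNSYYMRDIYITHCVDRHGNVSN
>F0014_OA_t1
FSEMTIHIFTHECGMVPSTPNHPPRWCWFHCGLYFGTWLVGAIHWCHILMRSLSTGGVHIIYPMQRSMTVWAVYGHCANCQAPSGFGSHATNVFALIVNNDKKRQWYIEHYVLVHGNYSR
>F0014_OB_t1
FSEMTIHIPYHCCGMPRGTINHPPDWCWFHCLLYFETWCVGAIHFCHTDMMALSLGGMHKIYPDQRSMVRWAVGGHRAAHQATAIHGGPLTNVFTLIVNNLKKRMTPIEHYVCVHGCPSR
>F0014_A1_t2
FGFMTIWIHFHECGCVRLTINVPSDWCWVHCLTRFETWCDGAQHPNHGDMQFSSTTLVWKIYPSGRCIVDWGVWCYGANAQAPAICGSPMTTMFEQ------------------------
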