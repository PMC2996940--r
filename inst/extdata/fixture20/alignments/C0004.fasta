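>F0004_A1_t1
FPVWYQHAKEGAKQNYEVQQAALGWAALLKSEYKFYFKFEPADIGVECMYSYMINTWIMLFDQSMMDTGVVSQPMLSPPDPVNQHSPHTWNVVFCWLEMHINQLTCTWVELKCLQIIPCC
>F0004_A2_t1
FDVWFQHAKEGAKQNYEVQQAALGWAALLKSEYKFYFKFEPADIGVECMYSYMINTWIMLFDQLVMDTGVVSQPMLSPPDPVNQHSPHTWNVPFCWLEGHINTLTCTWVELKCLQIIPCH
>F0004_B1_t1
TDQWWQHADRGAKWNLEVQQATLGWAPLLKIEHEFYFKFEPADIFNLCMYSYMINTWIMLRDMSVMDTGVNSQPMLSPPDPVNQESLHTANRVFCWDEGHIVKLTCTLVCLKCAQIIPCH
>F0004_B2_t1
TDQWWQHADAGAKWNMEVQQATLGWAPLKKIEHEFYFKFEPADIFNLCMYSYMINTWIMSRDGSVMDTGVVSQPMLSPPDPVNQESPHTANRVFCLDEGHIDHLTCTLVCLKCAQIIPCH
>F0004_OA_t1
CDQWFFHADKGIFGNLIVQQAADVGAALDKIEYKFMCKFEDACIGCLCMYSYMINTWITLGAQSAMKTGVNSHPRLSFPDHSNQDMVTTHNVVFCWLEGKINFLKGTWVCLTCLYIIPHH
>F0004_OB_t1
CDQWFSYAKKSAFQNGIVQQAADVGAANLKIEVAFMCKFENADSVCLGMYSYMINTWINLGHSSQMHTGVNSWPSLSEEDIVNQKWKTTHNVVFCWLEYDTNFLFGTWVCLWCLYIIHAH
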