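>F0002_A1_t1
LGRMDGNQDNRCNCNFWYTEENGTDFQPCYEHKCIWLRLTPRPHGCQWMFYSYMIMFLQCWNNIYQYCMDSTANACCGYAVDSIEPDHRRIDFNQERIWHHVGTVNCYSSGCVHVYGHGP
>F0002_B1_t1
LGRMKHNAHNSCNCNFWYTELNSTDTQPCYEHKCHWHNGTPRDHGCCSMFFSYYIVFEQCPNNDVQYMMPTVANACNGYHMDSSEIWHRRIYTNQQHKWHSHRTVNDYSSGCKHVIGHRP
>F0002_B2_t1
LGRMKHNRHNSCNCNFWYTELVSTDTQPCYEPKCHWHNGTPRDHGCWSMFFSYAIAFEQCPNNIYQYMMPTVANACNGYHMDSSEIWHRRIYTNQQHIWHSHRFVNDYSSGCKHVIGHRP
>F0002_OA_t1
LGRMDHNQDDAENCNTWTTFEESTQFSPCLMKFCHWHNSCCRDHFCISMNFSYTIMFSRAHCCIYETCMNSVSAACCGYMYDHSTPDHAFVKFNQRRILVSVDCVNDTSSGCVHGEGHGP
>F0002_OB_t1
LGRLDHDQDDEENNNQETTTEASTQFSPCYAHKCHWHNLCCYDHCCWEMFFSNTIMFCGCLCNIYEYKNANVSNACCFYDCDSTTIDHAFVDLNMRRIWVVVDYVNDTSSGCVVGWGAQP
>F0002_A1_t2
LGRMDGNQDNRCNCNFWYTEENGTDFQPCYEHKCIWLRLTPRPHGCQWMFYSYMIMFLQCWNNIYQYCMDSTANACCGYAVDSIEPDHRRIDFNQE------------------------
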