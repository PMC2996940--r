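>F0008_A1_t1
LDQCRQFQHVWSPSICIRWQWFCSFPEQFQIDGQSEDPFILYYFHKNSGLSDQAGPNSMYASLCIDLKKKDIGMPTACSRAISGKGKSELLKNNKMFISPIYLGPVHLYACTKKDDQDHW
>F0008_A2_t1
LDQCRQFQHVWSPSICIRWQWFHSFPEQFQIDGQSEDPFILRYGHKNSGLWDQATPPSMYASLWIDLKKKDFNIPTACSRAISGWGKSELLKNNKMFISPIFPGPVHLYVCTKKDDQDHW
>F0008_B1_t1
WRNCRQGQHEWSPPICIPWQWFHQFPEEFQIDGRSEDQFCLFYAHKSSGLWDQAGKPSMYASLWCDRKRKDFNSPGLDIHWISGIGRSEDWKNGSWFGSPLDPMPRHGYCFTGKDDQNHW
>F0008_OA_t1
FDQCFQNQHPWHPPDCTRWQWFHEFPEEFNFDVQSYDQFILCYAAKREGLRDQAGFPSMYSSLWRCRKKKLSRNPTLDDMAISVIGKNELMKYSADFISPVDWGRVHLLGCTTKDWQDMW
>F0008_OB_t1
FDQCFGNQKVWHPPICTRWQWSHEFPEEFHFDVQSEDQFHVTNAVKRNGLRDQAGKPSMYTSLWICRKKKLSRLPQGEDMAISYIGLMELMKYNDDSISTVDWARVHLLGCTFKPWQDRW
>F0008_B1_t2
WRNCRQGQHEWSPPICIPWQWFHQFPEEFQIDGRSEDQFCLFYAHKSSGLWDQAGKPSMYASLWCDRKRKDFNSPGLDIHWISGIGRSEDWKNGSW------------------------
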