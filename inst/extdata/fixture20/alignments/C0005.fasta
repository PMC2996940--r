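>F0005_A1_t1
QWVGSHMRNENDMRENCVRMDKCASEFEGAHGELQQKPERVSPHMEYDRVTGGSIVEALTCIDYNPPHRFNPRANKRTLCFDCHQMKILRSEMEPMKSPIDSECDEFEITEPKFQRQPWV
>F0005_B1_t1
QWVGSNMRHNMLVRENEVYMDKYASCFRYAHGELRQKPERKSPKTEHDRVTGGSGVEAFTCIDYNKKHRFWPRANKFTLCFDCADMVLLRSEMQPFKSEIFSECREFEITEPKQQSQYWV
>F0005_B2_t1
QWVISNMRHNMLVRENEVYMDKYASCFRYAHGELRQKPERKSPKTEQDRVTGGSGVEAFTCIDYNKKHREWPRANKFTLCFDCADMVLLFSEMQPFGSEIFSECREFEITEKWQQSQYWV
>F0005_OA_t1
QWQGLSMRHRMLMFENMVRMWFCASEWAFAHGRWQQKPGRKKPKYHYHWVRGSASVEALTPLHYNPKHRINPRADKFVLCFECTNIKTLRSGMLPFLSPIRSELWCFCIKELWQQNWVWA
>F0005_OB_t1
RIACDCMMINNLSRENEVPTDFCASRDYFAHGRWQQKPERKKPHYFYHWVNGSSSVEALTPIQYNRVQRIESRANKFVPCFHCVNICTLRCEMWPFKSQIRSEAREFCITEPKQQRWHWA
>F0005_A1_t2
QWVGSHMRNENDMRENCVRMDKCASEFEGAHGELQQKPERVSPHMEYDRVTGGSIVEALTCIDYNPPHRFNPRANKRTLCFDCHQMKILRSEMEPM------------------------
>F0005_OB_t2
RIACDCMMINNLSRENEVPTDFCASRDYFAHGRWQQKPERKKPHYFYHWVNGSSSVEALTPIQYNRVQRIESRANKFVPCFHCVNICTLRCEMWPF------------------------
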