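>F0016_A1_t1
GYSDTFRFWYEHPASPKAFYGPVQEVASQSMSPLKNHQSEVRSHLIMLHTFHFHMRHMVIPIHIEHFYTDEFCGINNMAQPHSVTYQGCKQKYDAMHAHAFFYGAEYHWGKPKMMAMIWH
>F0016_B1_t1
KYADTFMFLIRSPAGPKAFYGPVQEVASQSMFPLKWHQPDVRRHLIMLHTIHYHMRLMVIPIHIEQFYTDEFVGIYNYEQFHRVTYVGCKQKYDAYRAHAFFYGREYAWSKPDKMAVIAS
>F0016_B2_t1
KYHDTFMFQVRSPAGPKAFYGPVQEVASQCMFPLPWHQPDVRRHLIMLHTIHYHMRLMVFPIHIEQFYTDEFWGILNYEQCHRVTYVGCKQKYDAYRAHAFFYGREYAWSKPDKQAVIAS
>F0016_OA_t1
GTAHTFMFMIYHCNGAIASVANVCYVARQSMYPEKWHQFEHRSHNAMLHAFHFVRRHFVLNIGIEHGPQYKTCGIHNMAQPHSVFGSGCGMIYDAHLEHALTYRREWAWSLSDMMAVIAS
>F0016_OB_t1
GTADTFMFMIYHCKRAIAFYAPVCEVARMSMYPLKWHQLEHRSHLAILHALHFHRRHMVSPAGEEGAKTYKCCGIHNMYQPHSMFEFGFGMIYDAHHELFFTYRREYAWSLPDMMAVIAK
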