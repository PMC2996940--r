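>F0019_A1_t1
WCSGMYNAFNEPNVVRFAVMQACSTRDDVPQWAMLQKELGNARDPCIRCMNPPQIAGRNSIPVQQMTKKMQKIEHKAPRYAAIHHVQAPWCDLTYHCPWVLLRHDYWRHIQLFHVQKFDT
>F0019_B1_t1
WCSLNWHAFIEPNVVGFAWWQACSTYDDKPQVAVLQKMLGNATFCCIRCMNPPQIAGRDSIMVQQMTYKMDDIEHGAPRYAFIHHVDAFNGDKTYHCQRVQLRHDYHRHIQMFPVQKFDD
>F0019_B2_t1
WCSLNYHAFIEWNVVGFAHMQACSTRDDEPQHAVLQKMRGNATFCCIRCMNPPQIAGRDSITVQQMTYRMDKEEHGAPRYAFIHHVDAFNGDKTYHDQRVQLRHDYHRHIQMFPVQKFDD
>F0019_OA_t1
WCSGEYHAFIEPNEVSFAWHQFCTIRDSAPQWIAHFKMDWNAERPCNLCMFPCQIQQFDRIEEQQMTWKRDKIANWAPHYCCILHVQRPWFDKTYQCQRVSLRHDYPRHIQVFHHAVMRD
>F0019_OB_t1
WCSGEYHAFIEPNRVSFAWNQALTTRDDAPLWAVLLKMDWCFEFPCNQCMFPCQICYIDSGSIQCITWKRDAEEIWAMHYACIHHVQAPWGDKQYECTRVPLRGDYWWHIQVFHHAVFRP
>F0019_B2_t2
WCSLNYHAFIEWNVVGFAHMQACSTRDDEPQHAVLQKMRGNATFCCIRCMNPPQIAGRDSITVQQMTYRMDKEEHGAPRYAFIHHVDAFNGDKTYH------------------------
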