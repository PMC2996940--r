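>F0001_A1_t1
MCCPPDPQTFYFWHLYFKCVTLMWMKHQQPLLSVSPTAVGKGLLKCAARHADRDARWTIYSQWFDLVVGIEAPHYATGTIDMHVHVGFICAGDSIDIEADGIWFAFFMCWLAELWKMRID
>F0001_A2_t1
MCCPKDPQTVYFWSLYFKCVTWMAMKHQQPLLSVSPTAVGKGLGKCAARHADRDARWTIYSQWFDLMVGIEAPHYATGTIDMHVHVGFICAGDSIDIEADGISFAFFMCWLAELWKMRID
>F0001_B1_t1
MCCPHDPQTVYKTQPYFKCVTWMAIKFQQMLFSVSPTAYGKGLGYCADRHKDRDARWTICQQWFDQMVGKEAYHYHTDCIDMHLHVLPICAGDWIMLGFAGISFACILCWLAELNKMRIK
>F0001_B2_t1
MCCPHDPQTVYKTQLYFQCVCWMAEKSQQMLFSVSPTADEKGLGYCASRHADRDARWPICQQWFDQMVGIEAYHNAYGCIDMHLHVLFICAGDKLMLGFAGISFACILCWLAELWKMRCK
>F0001_OA_t1
MCCPKGPQIVQKNPIYFDCFCWCINKSFQYQASCSWVARGLGLGYCAAHTAWFDAQWGMYSQWMDVMMGIEANHYDTGTRDMHVHVLFVWVNDSIDIEFNGISFAEISCSLCELSKMTIT
>F0001_OB_t1
MACIKAGQLVKKNGIYFDEFCVSKLKSFFYFASVSAVARGCGEWYCAAHHADRLMQWAFYSQFFDVMVGIKAPHYDTGTWDNEVSVLRVWAESSIDFEHAGISRAEESHSLCELWKMGID
>F0001_A1_t2
MCCPPDPQTFYFWHLYFKCVTLMWMKHQQPLLSVSPTAVGKGLLKCAARHADRDARWTIYSQWFDLVVGIEAPHYATGTIDMHVHVGFICAGDSID------------------------
>F0001_B1_t2
MCCPHDPQTVYKTQPYFKCVTWMAIKFQQMLFSVSPTAYGKGLGYCADRHKDRDARWTICQQWFDQMVGKEAYHYHTDCIDMHLHVLPICAGDWIM------------------------
>F0001_OB_t2
MACIKAGQLVKKNGIYFDEFCVSKLKSFFYFASVSAVARGCGEWYCAAHHADRLMQWAFYSQFFDVMVGIKAPHYDTGTWDNEVSVLRVWAESSID------------------------
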