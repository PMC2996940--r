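gene_id	domain	start	repeat_type
F0001_A1	PF00008	50	FALSE
F0001_A1	PF00004	100	FALSE
F0001_A1	PF00008	150	FALSE
F0001_A2	PF00003	50	FALSE
F0001_A2	PF00007	100	FALSE
F0001_OA	PF00001	50	FALSE
F0002_A1	PF00010	50	FALSE
F0002_A1	PF00002	100	FALSE
F0002_OA	PF00009	50	FALSE
F0002_OA	PF00005	100	FALSE
F0002_OA	PF00005	150	FALSE
F0003_A1	PF00007	50	FALSE
F0003_A1	PF00010	100	FALSE
F0003_A1	PF00006	150	FALSE
F0003_OA	PF00002	50	FALSE
F0003_OA	PF00001	100	FALSE
F0004_A1	PF00010	50	FALSE
F0004_A2	PF00002	50	FALSE
F0004_A2	PF00005	100	FALSE
F0004_OA	PF00006	50	FALSE
F0004_OA	PF00003	100	FALSE
F0005_A1	PF00009	50	FALSE
F0005_A1	PFR0001	100	TRUE
F0005_A1	PFR0001	150	TRUE
F0005_A1	PFR0001	200	TRUE
F0005_A1	PFR0001	250	TRUE
F0005_OA	PF00007	50	FALSE
F0006_A1	PF00004	50	FALSE
F0006_A2	PF00004	50	FALSE
F0006_OA	PF00008	50	FALSE
F0006_OA	PFR0001	100	TRUE
F0006_OA	PFR0001	150	TRUE
F0006_OA	PFR0001	200	TRUE
F0007_A1	PF00004	50	FALSE
F0007_A1	PFR0001	100	TRUE
F0007_A1	PFR0001	150	TRUE
F0007_OA	PF00006	50	FALSE
F0008_A1	PF00006	50	FALSE
F0008_A1	PF00002	100	FALSE
F0008_A2	PF00010	50	FALSE
F0008_A2	PF00009	100	FALSE
F0008_A2	PF00003	150	FALSE
F0008_OA	PF00009	50	FALSE
F0008_OA	PF00001	100	FALSE
F0008_OA	PF00006	150	FALSE
F0009_A1	PF00001	50	FALSE
F0009_A1	PF00009	100	FALSE
F0009_OA	PF00005	50	FALSE
F0009_OA	PF00002	100	FALSE
F0009_OA	PFR0001	150	TRUE
F0009_OA	PFR0001	200	TRUE
F0010_A1	PF00005	50	FALSE
F0010_A1	PF00010	100	FALSE
F0010_A1	PFR0001	150	TRUE
F0010_A1	PFR0001	200	TRUE
F0010_A1	PFR0001	250	TRUE
F0010_A2	PF00007	50	FALSE
F0010_OA	PF00008	50	FALSE
F0010_OA	PF00004	100	FALSE
F0011_A1	PF00009	50	FALSE
F0011_A2	PF00009	50	FALSE
F0011_A2	PF00004	100	FALSE
F0011_A2	PF00003	150	FALSE
F0011_OA	PF00010	50	FALSE
F0012_A1	PF00008	50	FALSE
F0012_A2	PF00010	50	FALSE
F0012_A2	PF00008	100	FALSE
F0012_A2	PFR0001	150	TRUE
F0012_A2	PFR0001	200	TRUE
F0012_A2	PFR0001	250	TRUE
F0012_OA	PF00010	50	FALSE
F0012_OA	PF00006	100	FALSE
F0012_OA	PF00010	150	FALSE
F0013_A1	PF00002	50	FALSE
F0013_OA	PF00009	50	FALSE
F0013_OA	PF00007	100	FALSE
F0014_A1	PF00005	50	FALSE
F0014_A1	PF00010	100	FALSE
F0014_A1	PF00003	150	FALSE
F0014_OA	PF00005	50	FALSE
F0014_OA	PF00003	100	FALSE
F0014_OA	PF00001	150	FALSE
F0014_OA	PFR0001	200	TRUE
F0014_OA	PFR0001	250	TRUE
F0014_OA	PFR0001	300	TRUE
F0015_A1	PF00003	50	FALSE
F0015_A1	PFR0001	100	TRUE
F0015_A1	PFR0001	150	TRUE
F0015_A1	PFR0001	200	TRUE
F0015_A1	PFR0001	250	TRUE
F0015_OA	PF00003	50	FALSE
F0015_OA	PF00001	100	FALSE
F0015_OA	PF00008	150	FALSE
F0015_OA	PFR0001	200	TRUE
F0015_OA	PFR0001	250	TRUE
F0015_OA	PFR0001	300	TRUE
F0015_OA	PFR0001	350	TRUE
F0016_A1	PF00004	50	FALSE
F0016_A1	PF00007	100	FALSE
F0016_OA	PF00008	50	FALSE
F0016_OA	PF00009	100	FALSE
F0017_A1	PF00001	50	FALSE
F0017_A2	PF00007	50	FALSE
F0017_OA	PF00009	50	FALSE
F0017_OA	PF00003	100	FALSE
F0017_OA	PF00005	150	FALSE
F0018_A1	PF00008	50	FALSE
F0018_A1	PFR0001	100	TRUE
F0018_A1	PFR0001	150	TRUE
F0018_OA	PF00007	50	FALSE
F0018_OA	PF00002	100	FALSE
F0018_OA	PF00001	150	FALSE
F0019_A1	PF00003	50	FALSE
F0019_A1	PF00010	100	FALSE
F0019_A1	PF00005	150	FALSE
F0019_OA	PF00010	50	FALSE
F0019_OA	PF00006	100	FALSE
F0019_OA	PF00007	150	FALSE
F0020_A1	PF00010	50	FALSE
F0020_A1	PF00006	100	FALSE
F0020_OA	PF00007	50	FALSE
F0020_OA	PF00008	100	FALSE
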