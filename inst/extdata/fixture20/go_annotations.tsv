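gene_id	term
F0001_A1	GO:1000001
F0002_A1	GO:1000001
F0006_A2	GO:1000001
F0006_OA	GO:1000001
F0016_A1	GO:1000001
F0012_A2	GO:2000001
F0003_A1	GO:2000002
F0016_OA	GO:2000002
F0020_OA	GO:2000002
F0001_A2	GO:2000003
F0017_A2	GO:2000003
F0018_A1	GO:2000003
F0005_OA	GO:2000004
F0009_A1	GO:2000004
F0011_OA	GO:2000004
F0017_A1	GO:2000004
F0005_OA	GO:2000005
F0008_A1	GO:2000005
F0008_OA	GO:2000005
F0012_A2	GO:2000005
F0019_OA	GO:2000005
F0001_A1	GO:2000006
F0003_OA	GO:2000006
F0005_A1	GO:2000006
F0009_A1	GO:2000006
F0015_OA	GO:2000006
F0016_OA	GO:2000006
F0017_OA	GO:2000006
F0019_OA	GO:2000006
F0001_A2	GO:2000007
F0005_A1	GO:2000007
F0007_A1	GO:2000007
F0008_A1	GO:2000007
F0009_A1	GO:2000007
F0012_A1	GO:2000007
F0016_OA	GO:2000007
F0018_OA	GO:2000007
F0001_OA	GO:2000008
F0003_A1	GO:2000008
F0004_A1	GO:2000008
F0006_A1	GO:2000008
F0010_OA	GO:2000008
F0014_OA	GO:2000008
F0018_OA	GO:2000008
F0005_A1	GO:2000009
F0010_OA	GO:2000009
F0001_A2	GO:2000010
F0002_A1	GO:2000010
F0006_A1	GO:2000010
F0012_A2	GO:2000010
F0015_OA	GO:2000010
F0019_A1	GO:2000010
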