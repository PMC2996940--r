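family	gene_id	species	role	flagged
1	F0001_A1	spA	seed	FALSE
1	F0001_A2	spA	inparalog	FALSE
1	F0001_B1	spB	seed	FALSE
1	F0001_B2	spB	inparalog	FALSE
1	F0001_OA	spA	outparalog	FALSE
1	F0001_OB	spB	outparalog	FALSE
2	F0002_A1	spA	seed	FALSE
2	F0002_B1	spB	seed	FALSE
2	F0002_B2	spB	inparalog	FALSE
2	F0002_OA	spA	outparalog	FALSE
2	F0002_OB	spB	outparalog	FALSE
3	F0003_A1	spA	seed	FALSE
3	F0003_B1	spB	seed	FALSE
3	F0003_OA	spA	outparalog	FALSE
3	F0003_OB	spB	outparalog	FALSE
4	F0004_A1	spA	seed	FALSE
4	F0004_A2	spA	inparalog	FALSE
4	F0004_B1	spB	seed	FALSE
4	F0004_B2	spB	inparalog	FALSE
4	F0004_OA	spA	outparalog	FALSE
4	F0004_OB	spB	outparalog	FALSE
5	F0005_A1	spA	seed	FALSE
5	F0005_B1	spB	seed	FALSE
5	F0005_B2	spB	inparalog	FALSE
5	F0005_OA	spA	outparalog	FALSE
5	F0005_OB	spB	outparalog	FALSE
6	F0006_A1	spA	seed	FALSE
6	F0006_A2	spA	inparalog	FALSE
6	F0006_B1	spB	seed	FALSE
6	F0006_B2	spB	inparalog	FALSE
6	F0006_OA	spA	outparalog	FALSE
6	F0006_OB	spB	outparalog	FALSE
7	F0007_A1	spA	seed	FALSE
7	F0007_B1	spB	seed	FALSE
7	F0007_OA	spA	outparalog	FALSE
7	F0007_OB	spB	outparalog	FALSE
8	F0008_A1	spA	seed	FALSE
8	F0008_A2	spA	inparalog	FALSE
8	F0008_B1	spB	seed	FALSE
8	F0008_OA	spA	outparalog	FALSE
8	F0008_OB	spB	outparalog	FALSE
9	F0009_A1	spA	seed	FALSE
9	F0009_B1	spB	seed	FALSE
9	F0009_OA	spA	outparalog	FALSE
9	F0009_OB	spB	outparalog	FALSE
10	F0010_A1	spA	seed	FALSE
10	F0010_A2	spA	inparalog	FALSE
10	F0010_B1	spB	seed	FALSE
10	F0010_OA	spA	outparalog	FALSE
10	F0010_OB	spB	outparalog	FALSE
11	F0011_A1	spA	seed	FALSE
11	F0011_A2	spA	inparalog	FALSE
11	F0011_B1	spB	seed	FALSE
11	F0011_B2	spB	inparalog	FALSE
11	F0011_OA	spA	outparalog	FALSE
11	F0011_OB	spB	outparalog	FALSE
12	F0012_A1	spA	seed	FALSE
12	F0012_A2	spA	inparalog	FALSE
12	F0012_B1	spB	seed	FALSE
12	F0012_OA	spA	outparalog	FALSE
12	F0012_OB	spB	outparalog	FALSE
13	F0013_A1	spA	seed	FALSE
13	F0013_B1	spB	seed	FALSE
13	F0013_B2	spB	inparalog	FALSE
13	F0013_OA	spA	outparalog	FALSE
13	F0013_OB	spB	outparalog	FALSE
14	F0014_A1	spA	seed	FALSE
14	F0014_B1	spB	seed	FALSE
14	F0014_B2	spB	inparalog	FALSE
14	F0014_OA	spA	outparalog	FALSE
14	F0014_OB	spB	outparalog	FALSE
15	F0015_A1	spA	seed	FALSE
15	F0015_B1	spB	seed	FALSE
15	F0015_OA	spA	outparalog	FALSE
15	F0015_OB	spB	outparalog	FALSE
16	F0016_A1	spA	seed	FALSE
16	F0016_B1	spB	seed	FALSE
16	F0016_B2	spB	inparalog	FALSE
16	F0016_OA	spA	outparalog	FALSE
16	F0016_OB	spB	outparalog	FALSE
17	F0017_A1	spA	seed	FALSE
17	F0017_A2	spA	inparalog	FALSE
17	F0017_B1	spB	seed	FALSE
17	F0017_OA	spA	outparalog	FALSE
17	F0017_OB	spB	outparalog	FALSE
18	F0018_A1	spA	seed	FALSE
18	F0018_B1	spB	seed	FALSE
18	F0018_B2	spB	inparalog	FALSE
18	F0018_OA	spA	outparalog	FALSE
18	F0018_OB	spB	outparalog	FALSE
19	F0019_A1	spA	seed	FALSE
19	F0019_B1	spB	seed	FALSE
19	F0019_B2	spB	inparalog	FALSE
19	F0019_OA	spA	outparalog	FALSE
19	F0019_OB	spB	outparalog	FALSE
20	F0020_A1	spA	seed	FALSE
20	F0020_B1	spB	seed	FALSE
20	F0020_B2	spB	inparalog	FALSE
20	F0020_OA	spA	outparalog	FALSE
20	F0020_OB	spB	outparalog	FALSE
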