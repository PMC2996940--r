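cluster_id	species	member_id	confidence	is_seed	S	bootstrap
C0001	spA	F0001_A1	1	TRUE	181.2907	98
C0001	spA	F0001_A2	0.755	FALSE	181.2907	NA
C0001	spB	F0001_B1	1	TRUE	181.2907	92
C0001	spB	F0001_B2	0.648	FALSE	181.2907	NA
C0002	spA	F0002_A1	1	TRUE	184.2301	99
C0002	spB	F0002_B1	1	TRUE	184.2301	95
C0002	spB	F0002_B2	0.706	FALSE	184.2301	NA
C0003	spA	F0003_A1	1	TRUE	183.3963	98
C0003	spB	F0003_B1	1	TRUE	183.3963	94
C0004	spA	F0004_A1	1	TRUE	183.5807	94
C0004	spA	F0004_A2	0.368	FALSE	183.5807	NA
C0004	spB	F0004_B1	1	TRUE	183.5807	100
C0004	spB	F0004_B2	0.852	FALSE	183.5807	NA
C0005	spA	F0005_A1	1	TRUE	185.6023	60
C0005	spB	F0005_B1	1	TRUE	185.6023	87
C0005	spB	F0005_B2	0.321	FALSE	185.6023	NA
C0006	spA	F0006_A1	1	TRUE	181.8413	97
C0006	spA	F0006_A2	0.546	FALSE	181.8413	NA
C0006	spB	F0006_B1	1	TRUE	181.8413	93
C0006	spB	F0006_B2	0.384	FALSE	181.8413	NA
C0007	spA	F0007_A1	1	TRUE	184.9571	99
C0007	spB	F0007_B1	1	TRUE	184.9571	93
C0008	spA	F0008_A1	1	TRUE	181.7952	69
C0008	spA	F0008_A2	0.63	FALSE	181.7952	NA
C0008	spB	F0008_B1	1	TRUE	181.7952	79
C0009	spA	F0009_A1	1	TRUE	184.3409	99
C0009	spB	F0009_B1	1	TRUE	184.3409	92
C0010	spA	F0010_A1	1	TRUE	184.3652	68
C0010	spA	F0010_A2	0.351	FALSE	184.3652	NA
C0010	spB	F0010_B1	1	TRUE	184.3652	83
C0011	spA	F0011_A1	1	TRUE	182.3502	99
C0011	spA	F0011_A2	0.557	FALSE	182.3502	NA
C0011	spB	F0011_B1	1	TRUE	182.3502	96
C0011	spB	F0011_B2	0.913	FALSE	182.3502	NA
C0012	spA	F0012_A1	1	TRUE	184.4594	41
C0012	spA	F0012_A2	0.762	FALSE	184.4594	NA
C0012	spB	F0012_B1	1	TRUE	184.4594	57
C0013	spA	F0013_A1	1	TRUE	183.4625	96
C0013	spB	F0013_B1	1	TRUE	183.4625	92
C0013	spB	F0013_B2	0.835	FALSE	183.4625	NA
C0014	spA	F0014_A1	1	TRUE	185.0672	91
C0014	spB	F0014_B1	1	TRUE	185.0672	93
C0014	spB	F0014_B2	0.867	FALSE	185.0672	NA
C0015	spA	F0015_A1	1	TRUE	181.8355	92
C0015	spB	F0015_B1	1	TRUE	181.8355	95
C0016	spA	F0016_A1	1	TRUE	185.8894	99
C0016	spB	F0016_B1	1	TRUE	185.8894	93
C0016	spB	F0016_B2	0.446	FALSE	185.8894	NA
C0017	spA	F0017_A1	1	TRUE	181.4204	98
C0017	spA	F0017_A2	0.32	FALSE	181.4204	NA
C0017	spB	F0017_B1	1	TRUE	181.4204	97
C0018	spA	F0018_A1	1	TRUE	187.193	95
C0018	spB	F0018_B1	1	TRUE	187.193	91
C0018	spB	F0018_B2	0.51	FALSE	187.193	NA
C0019	spA	F0019_A1	1	TRUE	185.9009	98
C0019	spB	F0019_B1	1	TRUE	185.9009	97
C0019	spB	F0019_B2	0.343	FALSE	185.9009	NA
C0020	spA	F0020_A1	1	TRUE	181.7998	98
C0020	spB	F0020_B1	1	TRUE	181.7998	93
C0020	spB	F0020_B2	0.383	FALSE	181.7998	NA
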