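sample_id	rs1001_A	rs1002_A	rs1003_A
id000001	2	2	2
id000002	1	2	1
id000003	0	1	1
id000004	0	0	2
id000005	0	0	0
id000006	0	0	2
id000007	0	2	1
id000008	1	1	2
id000009	2	2	2
id000010	0	0	1
id000011	1	0	0
id000012	1	1	1
id000013	2	1	2
id000014	0	2	2
id000015	1	1	2
id000016	1	0	0
id000017	0	2	1
id000018	1	2	0
id000019	0	1	2
id000020	1	0	1
id000021	1	1	1
id000022	1	1	1
id000023	0	1	2
id000024	0	0	2
id000025	0	0	1
id000026	2	1	1
id000027	0	1	2
id000028	1	0	2
id000029	2	2	1
id000030	1	0	1
id000031	1	1	1
id000032	1	1	2
id000033	0	0	2
id000034	0	2	2
id000035	0	2	1
id000036	1	0	2
id000037	1	0	1
id000038	1	2	2
id000039	0	1	2
id000040	0	0	1
id000041	2	2	2
id000042	0	2	0
id000043	0	0	1
id000044	1	0	1
id000045	1	1	1
id000046	1	0	2
id000047	1	2	0
id000048	1	2	2
id000049	1	1	1
id000050	2	2	2
id000051	0	0	1
id000052	2	0	2
id000053	0	1	1
id000054	0	2	1
id000055	0	1	1
id000056	2	2	2
id000057	0	0	2
id000058	1	1	2
id000059	0	2	1
id000060	0	2	2
id000061	0	1	0
id000062	0	2	2
id000063	0	0	2
id000064	1	2	1
id000065	1	2	2
id000066	1	1	2
id000067	1	1	1
id000068	2	0	0
id000069	1	1	1
id000070	0	1	1
id000071	1	1	2
id000072	0	2	1
id000073	0	1	2
id000074	1	1	2
id000075	0	1	1
id000076	1	1	1
id000077	0	1	1
id000078	0	0	2
id000079	2	1	0
id000080	1	0	2
id000081	1	1	1
id000082	2	0	1
id000083	1	1	0
id000084	0	2	1
id000085	1	0	1
id000086	0	0	2
id000087	2	2	2
id000088	0	2	2
id000089	2	1	1
id000090	2	1	2
id000091	0	0	1
id000092	1	0	2
id000093	0	1	2
id000094	1	0	0
id000095	0	2	1
id000096	0	1	1
id000097	1	2	1
id000098	1	1	2
id000099	1	1	0
id000100	1	1	2
id000101	0	1	2
id000102	1	1	2
id000103	0	1	0
id000104	2	2	2
id000105	1	1	1
id000106	1	2	1
id000107	1	2	2
id000108	0	2	1
id000109	1	1	2
id000110	1	2	2
id000111	0	0	1
id000112	0	0	1
id000113	1	1	2
id000114	0	1	1
id000115	1	1	1
id000116	0	2	1
id000117	1	1	1
id000118	1	2	1
id000119	1	1	1
id000120	2	2	1
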