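sample_id	status
id000001	1
id000002	1
id000003	1
id000004	1
id000005	1
id000006	1
id000007	1
id000008	1
id000009	1
id000010	1
id000011	1
id000012	1
id000013	1
id000014	1
id000015	1
id000016	1
id000017	1
id000018	1
id000019	1
id000020	1
id000021	1
id000022	1
id000023	1
id000024	1
id000025	1
id000026	1
id000027	1
id000028	1
id000029	1
id000030	1
id000031	1
id000032	1
id000033	1
id000034	1
id000035	1
id000036	1
id000037	1
id000038	1
id000039	1
id000040	1
id000041	1
id000042	1
id000043	1
id000044	1
id000045	1
id000046	1
id000047	1
id000048	1
id000049	1
id000050	1
id000051	1
id000052	1
id000053	1
id000054	1
id000055	1
id000056	1
id000057	1
id000058	1
id000059	1
id000060	1
id000061	0
id000062	0
id000063	0
id000064	0
id000065	0
id000066	0
id000067	0
id000068	0
id000069	0
id000070	0
id000071	0
id000072	0
id000073	0
id000074	0
id000075	0
id000076	0
id000077	0
id000078	0
id000079	0
id000080	0
id000081	0
id000082	0
id000083	0
id000084	0
id000085	0
id000086	0
id000087	0
id000088	0
id000089	0
id000090	0
id000091	0
id000092	0
id000093	0
id000094	0
id000095	0
id000096	0
id000097	0
id000098	0
id000099	0
id000100	0
id000101	0
id000102	0
id000103	0
id000104	0
id000105	0
id000106	0
id000107	0
id000108	0
id000109	0
id000110	0
id000111	0
id000112	0
id000113	0
id000114	0
id000115	0
id000116	0
id000117	0
id000118	0
id000119	0
id000120	0
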