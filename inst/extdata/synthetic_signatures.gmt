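RepStress	placeholder replication-stress signature (synthetic gene ids)	g0001	g0002	g0003	g0004	g0005	g0006	g0007	g0008	g0009	g0010	g0011	g0012	g0013	g0014	g0015	g0016	g0017	g0018	g0019	g0020	g0021	g0022	g0023	g0024	g0025	g0026	g0027	g0028	g0029	g0030	g0031	g0032	g0033	g0034	g0035	g0036	g0037	g0038	g0039	g0040	g0041	g0042	g0043	g0044	g0045	g0046	g0047	g0048	g0049	g0050
PCa_IFN	placeholder interferon-response signature (synthetic gene ids)	g0051	g0052	g0053	g0054	g0055	g0056	g0057	g0058	g0059	g0060	g0061	g0062	g0063	g0064	g0065	g0066	g0067	g0068	g0069	g0070	g0071	g0072	g0073	g0074	g0075	g0076	g0077	g0078	g0079	g0080	g0081	g0082	g0083	g0084	g0085	g0086	g0087	g0088	g0089	g0090
RB1	placeholder RB1 functional-loss signature (synthetic gene ids)	g0091	g0092	g0093	g0094	g0095	g0096	g0097	g0098	g0099	g0100	g0101	g0102	g0103	g0104	g0105	g0106	g0107	g0108	g0109	g0110	g0111	g0112	g0113	g0114	g0115	g0116	g0117	g0118	g0119	g0120	g0121	g0122	g0123	g0124	g0125	g0126	g0127	g0128	g0129	g0130	g0131	g0132	g0133	g0134	g0135	g0136	g0137	g0138	g0139	g0140
AR	placeholder androgen-receptor signature (synthetic gene ids)	g0141	g0142	g0143	g0144	g0145	g0146	g0147	g0148	g0149	g0150	g0151	g0152	g0153	g0154	g0155	g0156	g0157	g0158	g0159	g0160	g0161	g0162	g0163	g0164	g0165	g0166	g0167	g0168	g0169	g0170	g0171	g0172	g0173	g0174	g0175	g0176	g0177	g0178	g0179	g0180
NE	placeholder neuroendocrine signature (synthetic gene ids)	g0181	g0182	g0183	g0184	g0185	g0186	g0187	g0188	g0189	g0190	g0191	g0192	g0193	g0194	g0195	g0196	g0197	g0198	g0199	g0200	g0201	g0202	g0203	g0204	g0205	g0206	g0207	g0208	g0209	g0210	g0211	g0212	g0213	g0214	g0215	g0216	g0217	g0218	g0219	g0220
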