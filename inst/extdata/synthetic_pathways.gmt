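SYN:0001	synthetic collagen matrix module	P001	P002	P003	P004	P005	P006	P007	P008
SYN:0002	synthetic inflammation module	P005	P008	P011	P014	P017	P020	P023	P026	P029
SYN:0003	synthetic metabolism module	P030	P034	P038	P042	P046	P050	P054	P058	P062	P066
SYN:0004	synthetic signalling module	P002	P013	P024	P035	P046	P057	P068	P079	P090	P101	P112
SYN:0005	synthetic broad background module	P001	P003	P005	P007	P009	P011	P013	P015	P017	P019	P021	P023	P025	P027	P029	P031	P033	P035	P037	P039	P041	P043	P045	P047	P049	P051	P053	P055	P057	P059	P061	P063	P065	P067	P069	P071	P073	P075	P077	P079	P081	P083	P085	P087	P089	P091	P093	P095	P097	P099	P101	P103	P105	P107	P109	P111	P113	P115	P117	P119	P121	P123	P125	P127	P129	P131	P133	P135	P137	P139	P141	P143	P145	P147	P149	P151	P153	P155	P157	P159	P161	P163	P165	P167	P169	P171	P173	P175	P177	P179	P181	P183	P185	P187	P189	P191	P193	P195	P197	P199	P201	P203	P205	P207	P209	P211	P213	P215	P217	P219	P221	P223	P225	P227	P229	P231	P233	P235	P237	P239	P241	P243	P245	P247	P249	P251	P253	P255	P257	P259	P261	P263	P265	P267	P269	P271	P273	P275
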