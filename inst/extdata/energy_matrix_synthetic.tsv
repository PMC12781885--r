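base	-41	-40	-39	-38	-37	-36	-35	-34	-33	-32	-31	-30	-29	-28	-27	-26	-25	-24	-23	-22	-21	-20	-19	-18	-17	-16	-15	-14	-13	-12	-11	-10	-9	-8	-7	-6	-5	-4	-3	-2	-1
A	0.2953	0.586	0.4354	0.3594	0.3364	0.361	-0.4104	0.0935	-0.3417	0.3917	0.1898	-0.1463	-0.4802	0.0754	-0.0447	0.4536	-0.4991	0.3369	0.1621	0.0624	-0.1823	0.4951	-0.1167	0.5273	-0.2245	-0.3131	0.1748	-0.4001	1.1064	0.1101	-0.2659	-0.488	-0.1245	0.5123	-0.4546	-0.3684	0.6201	-0.6621	-0.2468	-0.1588	-0.0852
C	-0.7233	-0.0217	0.0455	0.9433	-0.8356	0.2988	-0.2445	-0.1226	0.4942	0.4628	-0.1507	-0.0885	-1.6018	-0.7835	0.2289	0.0273	0.2562	-0.058	-0.2653	-0.553	0.5108	0.1977	0.2317	-0.081	0.238	-0.4503	0.5216	-0.4353	0.8307	-0.0257	-0.2806	0.8902	0.5258	0.1251	0.0794	-0.6559	-0.6302	-0.5587	-0.6721	-0.7474	-0.9372
G	0.0319	0.2977	-0.4427	-0.3975	-0.271	0.6241	0.0617	0.5178	0.3927	0.1298	0.2612	0.2418	0.0956	0.3278	0.2211	-0.311	0.5534	-0.6253	-0.1151	-0.2041	-0.1668	1.0302	0.7202	-0.2499	0.9054	0.4844	0.7233	0.0906	-0.6731	-0.7332	-0.0781	-0.2681	0.256	-0.5793	0.167	-0.3674	-0.0014	-0.3409	-0.1775	0.2045	-0.5689
T	-0.5118	-0.1297	0.3953	0.4977	-0.6462	0.2097	1.1349	0.1554	0.5659	-0.3025	0.0375	-0.3367	0.0539	0.1643	-0.3885	0.3344	0.4702	-0.6541	0.8618	0.7191	0.6237	-0.3565	0.3128	-0.4514	0.0435	0.4936	0.5477	0.4053	0.6532	0.0434	-0.4051	1.2474	-0.0124	-0.0795	-0.3224	0.8227	0.1503	-0.6294	-1.6071	-0.4988	-0.2143
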