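chr14	105865406	105865458	IGHJ1	0	-
chr14	105864796	105864849	IGHJ2	0	-
chr14	105864190	105864240	IGHJ3	0	-
chr14	105863583	105863631	IGHJ4	0	-
chr14	105862971	105863022	IGHJ5	0	-
chr14	105862350	105862413	IGHJ6	0	-
chr14	105865530	105865541	IGHD7-27	0	-
chr14	105880460	105880480	IGHD1-26	0	-
chr14	105882500	105882517	IGHD6-25	0	-
chr14	105884804	105884827	IGHD5-24	0	-
chr14	105887108	105887139	IGHD4-23	0	-
chr14	105889412	105889428	IGHD3-22	0	-
chr14	105891717	105891745	IGHD2-21	0	-
chr14	105894021	105894042	IGHD1-20	0	-
chr14	105896325	105896362	IGHD6-19	0	-
chr14	105898629	105898648	IGHD5-18	0	-
chr14	105900933	105900958	IGHD4-17	0	-
chr14	105903238	105903271	IGHD3-16	0	-
chr14	105905542	105905565	IGHD2-15	0	-
chr14	105907846	105907858	IGHD1-14	0	-
chr14	105910150	105910177	IGHD6-13	0	-
chr14	105912454	105912485	IGHD5-12	0	-
chr14	105914758	105914779	IGHD4-11	0	-
chr14	105917062	105917078	IGHD3-10	0	-
chr14	105919367	105919398	IGHD3-9	0	-
chr14	105921671	105921707	IGHD2-8	0	-
chr14	105923975	105923998	IGHD1-7	0	-
chr14	105926279	105926307	IGHD6-6	0	-
chr14	105928583	105928604	IGHD5-5	0	-
chr14	105930888	105930921	IGHD4-4	0	-
chr14	105933192	105933223	IGHD3-3	0	-
chr14	105935496	105935520	IGHD2-2	0	-
chr14	105937800	105937822	IGHD1-1	0	-
chr14	105939756	105940206	IGHV6-1	0	-
chr14	105960000	105960450	IGHV1-2	0	-
chr14	105979167	105979617	IGHV1-3	0	-
chr14	105998333	105998783	IGHV4-4	0	-
chr14	106017500	106017950	IGHV2-5	0	-
chr14	106036667	106037117	IGHV3-7	0	-
chr14	106055833	106056283	IGHV1-8	0	-
chr14	106075000	106075450	IGHV3-9	0	-
chr14	106094167	106094617	IGHV3-11	0	-
chr14	106113333	106113783	IGHV3-13	0	-
chr14	106132500	106132950	IGHV3-15	0	-
chr14	106151667	106152117	IGHV3-16	0	-
chr14	106170833	106171283	IGHV1-18	0	-
chr14	106190000	106190450	IGHV3-20	0	-
chr14	106209167	106209617	IGHV3-21	0	-
chr14	106228333	106228783	IGHV3-23	0	-
chr14	106247500	106247950	IGHV1-24	0	-
chr14	106266667	106267117	IGHV2-25	0	-
chr14	106285833	106286283	IGHV2-26	0	-
chr14	106305000	106305450	IGHV4-28	0	-
chr14	106324167	106324617	IGHV3-29	0	-
chr14	106343333	106343783	IGHV3-30	0	-
chr14	106362500	106362950	IGHV4-31	0	-
chr14	106381667	106382117	IGHV3-32	0	-
chr14	106400833	106401283	IGHV3-33	0	-
chr14	106420000	106420450	IGHV4-34	0	-
chr14	106439167	106439617	IGHV3-36	0	-
chr14	106458333	106458783	IGHV3-38	0	-
chr14	106477500	106477950	IGHV4-39	0	-
chr14	106496667	106497117	IGHV3-41	0	-
chr14	106515833	106516283	IGHV3-43	0	-
chr14	106535000	106535450	IGHV1-45	0	-
chr14	106554167	106554617	IGHV1-46	0	-
chr14	106573333	106573783	IGHV3-47	0	-
chr14	106592500	106592950	IGHV3-48	0	-
chr14	106611667	106612117	IGHV3-49	0	-
chr14	106630833	106631283	IGHV5-51	0	-
chr14	106650000	106650450	IGHV3-52	0	-
chr14	106669167	106669617	IGHV3-53	0	-
chr14	106688333	106688783	IGHV4-55	0	-
chr14	106707500	106707950	IGHV3-57	0	-
chr14	106726667	106727117	IGHV1-58	0	-
chr14	106745833	106746283	IGHV4-59	0	-
chr14	106765000	106765450	IGHV3-60	0	-
chr14	106784167	106784617	IGHV4-61	0	-
chr14	106803333	106803783	IGHV3-64	0	-
chr14	106822500	106822950	IGHV3-66	0	-
chr14	106841667	106842117	IGHV1-69	0	-
chr14	106860833	106861283	IGHV2-70	0	-
chr14	106880000	106880450	IGHV3-72	0	-
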