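slide_id,cell_id,vimentin,cd3,tissue_class,manual_pos_cd3,tumor_region
s01,cell_000001,57,38,epithelium,0,1
s01,cell_000002,11,35,epithelium,0,0
s01,cell_000003,220,48,stroma,0,0
s01,cell_000004,16,34,epithelium,0,0
s01,cell_000005,7,282,epithelium,1,0
s01,cell_000006,12,25,epithelium,0,0
s01,cell_000007,5,216,epithelium,1,1
s01,cell_000008,14,27,epithelium,0,0
s01,cell_000009,25,36,epithelium,0,0
s01,cell_000010,34,36,epithelium,0,0
s01,cell_000011,186,136,stroma,1,0
s01,cell_000012,252,230,stroma,1,1
s01,cell_000013,28,33,epithelium,0,0
s01,cell_000014,44,24,epithelium,0,0
s01,cell_000015,196,233,stroma,1,0
s01,cell_000016,30,49,epithelium,0,1
s01,cell_000017,17,184,epithelium,1,0
s01,cell_000018,66,20,stroma,0,0
s01,cell_000019,20,39,epithelium,0,1
s01,cell_000020,210,29,stroma,0,1
s01,cell_000021,35,24,epithelium,0,1
s01,cell_000022,23,126,epithelium,1,1
s01,cell_000023,43,145,epithelium,1,1
s01,cell_000024,19,168,epithelium,1,1
s01,cell_000025,267,20,stroma,0,0
s01,cell_000026,43,14,epithelium,0,0
s01,cell_000027,286,72,stroma,0,0
s01,cell_000028,268,214,stroma,1,1
s01,cell_000029,138,217,stroma,1,0
s01,cell_000030,11,298,epithelium,1,1
s01,cell_000031,23,18,epithelium,0,0
s01,cell_000032,68,30,stroma,0,0
s01,cell_000033,29,268,epithelium,1,0
s01,cell_000034,20,40,epithelium,0,0
s01,cell_000035,231,30,stroma,0,0
s01,cell_000036,204,549,stroma,1,0
s01,cell_000037,29,23,epithelium,0,1
s01,cell_000038,39,40,epithelium,0,1
s01,cell_000039,40,44,epithelium,0,0
s01,cell_000040,18,23,epithelium,0,1
s01,cell_000041,184,33,stroma,0,0
s01,cell_000042,307,25,stroma,0,1
s01,cell_000043,23,199,epithelium,1,0
s01,cell_000044,114,33,stroma,0,0
s01,cell_000045,26,43,epithelium,0,0
s01,cell_000046,27,63,epithelium,0,0
s01,cell_000047,41,30,epithelium,0,0
s01,cell_000048,23,288,epithelium,1,0
s01,cell_000049,136,181,stroma,1,0
s01,cell_000050,22,50,epithelium,0,0
s01,cell_000051,23,226,epithelium,1,0
s01,cell_000052,51,32,epithelium,0,1
s01,cell_000053,18,43,epithelium,0,0
s01,cell_000054,23,44,epithelium,0,0
s01,cell_000055,29,29,epithelium,0,0
s01,cell_000056,42,287,epithelium,1,1
s01,cell_000057,23,60,epithelium,0,0
s01,cell_000058,206,133,stroma,1,1
s01,cell_000059,255,41,stroma,0,0
s01,cell_000060,202,239,stroma,1,1
s02,cell_000061,19,20,epithelium,0,0
s02,cell_000062,490,90,stroma,1,0
s02,cell_000063,250,17,stroma,0,0
s02,cell_000064,14,17,epithelium,0,1
s02,cell_000065,204,11,stroma,0,1
s02,cell_000066,36,31,epithelium,0,1
s02,cell_000067,215,292,stroma,1,0
s02,cell_000068,37,144,epithelium,1,1
s02,cell_000069,17,55,epithelium,0,1
s02,cell_000070,27,40,epithelium,0,1
s02,cell_000071,21,52,epithelium,0,0
s02,cell_000072,46,156,epithelium,1,0
s02,cell_000073,125,20,stroma,0,1
s02,cell_000074,23,208,epithelium,1,0
s02,cell_000075,22,142,epithelium,1,1
s02,cell_000076,657,85,stroma,1,1
s02,cell_000077,56,25,epithelium,0,0
s02,cell_000078,130,83,epithelium,1,0
s02,cell_000079,152,23,stroma,0,0
s02,cell_000080,48,17,epithelium,0,0
s02,cell_000081,28,162,epithelium,1,0
s02,cell_000082,9,150,epithelium,1,1
s02,cell_000083,27,99,epithelium,1,0
s02,cell_000084,460,11,stroma,0,0
s02,cell_000085,248,29,stroma,0,1
s02,cell_000086,167,35,stroma,0,0
s02,cell_000087,40,13,epithelium,0,0
s02,cell_000088,12,111,epithelium,1,0
s02,cell_000089,94,178,epithelium,1,1
s02,cell_000090,110,148,stroma,1,0
s02,cell_000091,23,25,epithelium,0,0
s02,cell_000092,29,24,epithelium,0,0
s02,cell_000093,56,148,epithelium,1,0
s02,cell_000094,24,21,epithelium,0,1
s02,cell_000095,480,20,stroma,0,0
s02,cell_000096,10,69,epithelium,0,1
s02,cell_000097,47,25,epithelium,0,0
s02,cell_000098,24,10,epithelium,0,1
s02,cell_000099,34,30,epithelium,0,0
s02,cell_000100,17,12,epithelium,0,0
s02,cell_000101,80,432,stroma,1,0
s02,cell_000102,134,11,stroma,0,0
s02,cell_000103,24,56,epithelium,1,0
s02,cell_000104,41,18,epithelium,0,0
s02,cell_000105,19,18,epithelium,0,0
s02,cell_000106,487,10,stroma,0,0
s02,cell_000107,412,178,stroma,1,0
s02,cell_000108,21,306,epithelium,1,0
s02,cell_000109,55,12,epithelium,0,0
s02,cell_000110,17,160,epithelium,1,1
s02,cell_000111,15,98,epithelium,1,0
s02,cell_000112,35,26,epithelium,0,1
s02,cell_000113,67,30,epithelium,0,0
s02,cell_000114,60,32,stroma,0,1
s02,cell_000115,425,11,stroma,0,1
s02,cell_000116,151,28,stroma,0,1
s02,cell_000117,92,16,stroma,0,0
s02,cell_000118,41,24,epithelium,0,0
s02,cell_000119,395,22,stroma,0,1
s02,cell_000120,13,14,epithelium,0,0
s03,cell_000121,32,747,epithelium,1,0
s03,cell_000122,100,88,stroma,0,0
s03,cell_000123,30,494,epithelium,1,1
s03,cell_000124,22,151,epithelium,0,1
s03,cell_000125,16,28,epithelium,0,0
s03,cell_000126,288,167,stroma,0,1
s03,cell_000127,21,64,epithelium,0,0
s03,cell_000128,33,69,epithelium,0,1
s03,cell_000129,32,414,epithelium,1,0
s03,cell_000130,53,27,epithelium,0,0
s03,cell_000131,36,436,epithelium,1,0
s03,cell_000132,37,60,epithelium,0,0
s03,cell_000133,33,41,epithelium,0,1
s03,cell_000134,29,73,epithelium,0,0
s03,cell_000135,258,324,stroma,1,0
s03,cell_000136,15,246,epithelium,1,1
s03,cell_000137,20,93,epithelium,0,0
s03,cell_000138,134,110,stroma,0,1
s03,cell_000139,82,32,stroma,0,0
s03,cell_000140,199,44,stroma,0,0
s03,cell_000141,18,20,epithelium,0,1
s03,cell_000142,205,38,stroma,0,0
s03,cell_000143,150,427,stroma,1,0
s03,cell_000144,19,103,epithelium,0,1
s03,cell_000145,11,72,epithelium,0,0
s03,cell_000146,12,424,epithelium,1,1
s03,cell_000147,30,125,epithelium,0,1
s03,cell_000148,338,101,stroma,0,1
s03,cell_000149,14,337,epithelium,1,0
s03,cell_000150,241,47,stroma,0,0
s03,cell_000151,28,86,epithelium,0,0
s03,cell_000152,20,309,epithelium,1,0
s03,cell_000153,150,46,stroma,0,0
s03,cell_000154,14,72,epithelium,0,0
s03,cell_000155,45,39,epithelium,0,1
s03,cell_000156,104,38,stroma,0,0
s03,cell_000157,35,75,epithelium,0,0
s03,cell_000158,24,627,epithelium,1,0
s03,cell_000159,26,575,epithelium,1,0
s03,cell_000160,159,555,stroma,1,1
s03,cell_000161,41,32,stroma,0,1
s03,cell_000162,34,25,epithelium,0,0
s03,cell_000163,222,43,stroma,0,0
s03,cell_000164,352,457,stroma,1,0
s03,cell_000165,20,365,epithelium,1,1
s03,cell_000166,15,514,epithelium,1,0
s03,cell_000167,110,25,stroma,0,0
s03,cell_000168,145,158,stroma,0,0
s03,cell_000169,20,59,epithelium,0,0
s03,cell_000170,131,57,stroma,0,0
s03,cell_000171,43,319,epithelium,1,0
s03,cell_000172,324,97,stroma,0,0
s03,cell_000173,17,26,epithelium,0,0
s03,cell_000174,250,131,stroma,0,0
s03,cell_000175,33,39,epithelium,0,1
s03,cell_000176,135,44,stroma,0,0
s03,cell_000177,20,42,epithelium,0,0
s03,cell_000178,158,80,stroma,0,0
s03,cell_000179,24,773,epithelium,1,0
s03,cell_000180,359,107,stroma,0,1
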