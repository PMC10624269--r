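country,income_group,population,data_available,deaths_MAL,deaths_HIV,deaths_TB,deaths_STROKE,deaths_DEM,deaths_CIHD,deaths_NIHD,deaths_LUNG,deaths_LIVER,deaths_RENAL,deaths_CNSI,deaths_CNSD,deaths_INJ,deaths_POIS,deaths_MSK,deaths_CONG,deaths_PREM,deaths_HEMF,deaths_PEM,deaths_ATH,cases_MAL,cases_HIV,cases_TB,cases_STROKE,cases_DEM,cases_CIHD,cases_NIHD,cases_LUNG,cases_LIVER,cases_RENAL,cases_CNSI,cases_CNSD,cases_INJ,cases_POIS,cases_MSK,cases_CONG,cases_PREM,cases_HEMF,cases_PEM,cases_ATH
LIC_01,low,8899211,TRUE,682,43292,743,614,170,671,412,342,309,305,267,160,1029,166,127,413,732,153,426,164,1525,500021,2498,1543,1345,2429,1180,1593,1088,1439,371,591,3753,152,1314,3405,484,98,1521,425
LIC_02,low,5005392,TRUE,2854,1573,1418,1787,515,1520,1551,786,1022,846,668,497,2934,424,409,958,1919,385,932,456,5396,13516,5877,6565,3042,7765,4599,2799,2362,4135,1388,2383,10258,302,3166,4622,2288,233,3817,1428
LIC_03,low,14457570,TRUE,5636,3730,4969,5171,1267,4824,2471,2033,2374,1869,1988,1016,7547,1204,1242,3382,5624,1402,2696,1060,16077,24213,13574,12904,8224,21039,6030,8071,12396,8155,3343,5856,31377,902,11359,22325,7490,727,12986,3286
LMC_01,lower-middle,2133663,TRUE,911,192,399,901,265,627,441,465,353,399,128,135,792,170,167,265,484,66,210,182,1891,1740,1036,2410,1279,2503,1112,1317,989,1750,281,468,4178,220,1213,1702,494,34,873,619
LMC_02,lower-middle,2694074,TRUE,978,272,407,615,261,1184,635,623,436,408,191,155,961,174,163,279,532,84,290,296,2459,2240,995,2321,2156,6619,2256,4389,1601,1309,273,741,3893,203,1271,1732,334,45,1135,734
LMC_03,lower-middle,162453266,TRUE,76416,16556,29251,59197,14762,57485,35811,32385,27009,24429,13866,10701,58251,13954,12934,24856,29343,6124,15529,17460,166076,98920,59559,223241,108273,193351,110119,126644,142265,110415,35831,48339,369261,11585,126602,159581,26762,4560,55570,46533
LMC_04,lower-middle,2978666,TRUE,1392,319,582,1114,331,963,560,579,578,436,199,256,861,268,167,392,641,102,399,323,3560,1701,1845,3186,2142,5344,1821,2719,2045,1751,320,999,2270,358,1294,2682,523,67,1582,969
LMC_05,lower-middle,7602913,TRUE,3390,816,1236,2213,689,2460,1896,1695,1500,1204,664,482,2230,514,463,855,1666,292,633,777,7109,5284,4913,5343,3690,8021,6840,8357,8006,5580,1397,2017,7078,464,3712,4283,1380,147,1956,2311
LMC_06,lower-middle,115459146,TRUE,55679,12800,20076,37761,13870,45201,23255,27975,17921,17145,7532,7046,41186,8706,6939,16532,29218,3511,11790,11075,103510,88521,63611,111900,65285,153711,99730,118300,57664,87990,14646,31812,186634,13891,71293,98629,38466,1207,50491,33669
LMC_07,lower-middle,3527462,TRUE,1843,410,607,1042,378,1034,868,770,639,398,217,252,1603,216,239,440,719,123,432,481,4598,3273,2118,2819,1725,4094,2512,4046,1599,1375,314,1312,4729,247,2557,2283,739,63,2424,1334
UMC_01,upper-middle,3895192,TRUE,1872,319,375,1137,682,1144,864,601,753,410,272,339,856,228,299,386,277,121,115,275,3008,3023,1050,2329,3084,4476,2397,1797,2660,1618,481,1755,2032,222,2433,2253,305,49,442,893
UMC_02,upper-middle,10707396,TRUE,4762,592,1305,3163,1526,3734,2553,2348,1431,821,545,1066,2404,762,716,974,997,328,321,782,10446,4389,3509,9694,8698,17712,8850,11749,3891,4036,1059,3309,15937,689,7485,6842,741,177,1319,2278
UMC_03,upper-middle,63211521,TRUE,30367,3230,4859,17244,10147,22453,10984,14015,7522,7528,4311,6167,14974,2693,3663,6151,4709,2153,1888,3284,46262,23258,15278,40877,47650,104290,39914,112029,20294,35472,8017,24723,64599,2724,39658,30714,6371,1251,5255,13707
UMC_04,upper-middle,51048509,TRUE,27616,2896,5130,12656,6899,19100,11604,8324,6281,7444,2788,4556,12777,3925,3344,5107,5814,1484,2260,3292,38104,21940,14499,53831,43206,82588,26867,42155,21395,27219,6425,20168,51399,2943,44770,40152,5937,798,9626,14069
UMC_05,upper-middle,32693943,TRUE,17256,1824,3190,9259,4731,14100,8085,8278,4431,3203,2089,3173,7974,2334,2818,3719,2811,986,1199,1551,31605,12927,8090,25649,28773,54341,25957,51671,8781,15986,3826,17534,27694,3000,22330,24962,4285,423,5769,4732
HIC_01,high,8300016,TRUE,3447,166,131,1552,1235,2022,1150,979,604,554,150,580,1116,140,320,377,255,90,64,573,6632,1245,464,5088,8795,10541,2742,4498,1744,2849,336,2659,5070,152,2442,2949,350,43,241,1995
HIC_02,high,5913128,TRUE,3262,106,110,996,1366,1640,1126,941,421,586,107,596,1034,131,239,209,236,82,68,396,8626,807,442,3271,7615,7182,2715,5361,1313,2075,194,2785,5225,134,2965,1516,238,57,289,1247
HIC_03,high,3385779,TRUE,1645,73,68,586,591,901,646,479,226,270,69,303,452,66,133,113,142,36,38,196,3356,494,236,1733,4004,3543,1302,2696,523,815,142,1003,1698,67,1652,811,135,24,212,601
HIC_04,high,1788880,TRUE,891,30,37,256,406,361,227,255,135,112,44,157,165,22,79,69,66,19,17,99,1741,200,85,814,1757,1423,741,1047,423,627,121,757,572,14,765,473,63,12,58,318
HIC_05,high,5877648,TRUE,2596,115,131,987,937,1209,790,785,500,516,95,422,839,113,256,222,260,63,50,398,5975,937,418,2332,5781,3695,3336,4157,1412,1587,211,2387,2604,201,3204,1456,205,32,253,1330
HIC_06,high,2120117,TRUE,1012,34,46,437,373,654,246,417,196,164,40,161,315,43,69,61,69,17,18,118,2133,377,135,879,2122,2514,537,2097,478,546,80,874,1286,46,443,495,141,10,72,339
NDC_01,low,,FALSE,,,,,,,,,,,,,,,,,,,,,,,,,,,,,,,,,,,,,,,,
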