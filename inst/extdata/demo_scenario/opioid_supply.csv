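country,opioid,route_class,quantity_mg
LIC_01,morphine,oral,59276.225022383464
LIC_01,oxycodone,oral,166927.45095068362
LIC_01,hydromorphone,oral,54511.033451290808
LIC_01,morphine,parenteral,53139.541554410331
LIC_01,fentanyl,transdermal,7332.57676426947
LIC_01,methadone,oral,479393.11848720536
LIC_02,morphine,oral,109225.92281099943
LIC_02,oxycodone,oral,51064.960825112736
LIC_02,hydromorphone,oral,15721.724229846781
LIC_02,morphine,parenteral,16545.899657010246
LIC_02,fentanyl,transdermal,265.73916029663656
LIC_02,methadone,oral,752421.34315194562
LIC_03,morphine,oral,142349.43706604265
LIC_03,oxycodone,oral,69823.377342014806
LIC_03,hydromorphone,oral,93323.872716482263
LIC_03,morphine,parenteral,28800.43397658422
LIC_03,fentanyl,transdermal,1291.5826053150347
LIC_03,methadone,oral,224083.83829519153
LMC_01,morphine,oral,164743.02895135598
LMC_01,oxycodone,oral,10218.313786574925
LMC_01,hydromorphone,oral,278563.96472050407
LMC_01,morphine,parenteral,161336.33843869428
LMC_01,fentanyl,transdermal,2253.5000054568281
LMC_01,methadone,oral,422404.62351124734
LMC_02,morphine,oral,197475.82442701058
LMC_02,oxycodone,oral,329201.92805895099
LMC_02,hydromorphone,oral,172681.61307675403
LMC_02,morphine,parenteral,179016.39446502295
LMC_02,fentanyl,transdermal,5584.2136840747817
LMC_02,methadone,oral,146317.17436248437
LMC_03,morphine,oral,62414235.015699349
LMC_03,oxycodone,oral,27301636.348540064
LMC_03,hydromorphone,oral,8874905.0014946833
LMC_03,morphine,parenteral,4803636.2445326438
LMC_03,fentanyl,transdermal,52403.25438788913
LMC_03,methadone,oral,922640.37530403584
LMC_04,morphine,oral,1477178.9598716211
LMC_04,oxycodone,oral,489683.16036527109
LMC_04,hydromorphone,oral,24084.544813016611
LMC_04,morphine,parenteral,62153.518332607251
LMC_04,fentanyl,transdermal,4040.8044470558434
LMC_04,methadone,oral,216566.51536002755
LMC_05,morphine,oral,198577.04023890485
LMC_05,oxycodone,oral,2522749.240634799
LMC_05,hydromorphone,oral,240126.30003532834
LMC_05,morphine,parenteral,295449.25102563453
LMC_05,fentanyl,transdermal,11153.748143406796
LMC_05,methadone,oral,340830.02385683358
LMC_06,morphine,oral,1944954.0377639201
LMC_06,oxycodone,oral,47949221.989113808
LMC_06,hydromorphone,oral,1267954.3136071155
LMC_06,morphine,parenteral,10253435.768863041
LMC_06,fentanyl,transdermal,33925.745781728059
LMC_06,methadone,oral,82137.350144330412
LMC_07,morphine,oral,442124.69538597565
LMC_07,oxycodone,oral,490787.16179413401
LMC_07,hydromorphone,oral,134584.54084438027
LMC_07,morphine,parenteral,45947.512189132736
LMC_07,fentanyl,transdermal,16520.765607279045
LMC_07,methadone,oral,26102.534846868366
UMC_01,morphine,oral,119843.08886913772
UMC_01,oxycodone,oral,4202257.4360695621
UMC_01,hydromorphone,oral,585539.68336504139
UMC_01,morphine,parenteral,780118.84988676163
UMC_01,fentanyl,transdermal,47861.161145310703
UMC_01,methadone,oral,135330.16820438206
UMC_02,morphine,oral,18944426.509500179
UMC_02,oxycodone,oral,1278716.436771722
UMC_02,hydromorphone,oral,1601318.9906191714
UMC_02,morphine,parenteral,3923564.7643434405
UMC_02,fentanyl,transdermal,56610.522048352323
UMC_02,methadone,oral,228016.95983624086
UMC_03,morphine,oral,2579246.4733623788
UMC_03,oxycodone,oral,42008420.754741393
UMC_03,hydromorphone,oral,6773082.2068086015
UMC_03,morphine,parenteral,13720968.054514224
UMC_03,fentanyl,transdermal,1265233.0010374847
UMC_03,methadone,oral,749191.0310741514
UMC_04,morphine,oral,6210517.0988235334
UMC_04,oxycodone,oral,29156895.551174592
UMC_04,hydromorphone,oral,10571132.99914524
UMC_04,morphine,parenteral,1251582.3066110124
UMC_04,fentanyl,transdermal,1249525.4734550063
UMC_04,methadone,oral,971930.44719053432
UMC_05,morphine,oral,7584582.0619600005
UMC_05,oxycodone,oral,22430366.59695977
UMC_05,hydromorphone,oral,977794.86252210534
UMC_05,morphine,parenteral,12116249.247692483
UMC_05,fentanyl,transdermal,677309.11586934491
UMC_05,methadone,oral,552404.33088270947
HIC_01,morphine,oral,11304191.743240241
HIC_01,oxycodone,oral,2924970.5546393399
HIC_01,hydromorphone,oral,818269.38559956092
HIC_01,morphine,parenteral,13026009.642109238
HIC_01,fentanyl,transdermal,150628.0667794981
HIC_01,methadone,oral,215666.33642651141
HIC_02,morphine,oral,3019619.4098447827
HIC_02,oxycodone,oral,3608774.5071609891
HIC_02,hydromorphone,oral,7584565.3336243508
HIC_02,morphine,parenteral,5518871.6548913335
HIC_02,fentanyl,transdermal,116982.50927117327
HIC_02,methadone,oral,628676.54628120363
HIC_03,morphine,oral,12984681.305274086
HIC_03,oxycodone,oral,950041.18877111655
HIC_03,hydromorphone,oral,3285948.3514054148
HIC_03,morphine,parenteral,177676.61614854456
HIC_03,fentanyl,transdermal,51680.626700019508
HIC_03,methadone,oral,243297.13979270309
HIC_04,morphine,oral,3537297.3387206397
HIC_04,oxycodone,oral,767009.80729667749
HIC_04,hydromorphone,oral,628456.99336124852
HIC_04,morphine,parenteral,1836338.8264132673
HIC_04,fentanyl,transdermal,40920.34047649549
HIC_04,methadone,oral,314339.43533804268
HIC_05,morphine,oral,8108688.9049304249
HIC_05,oxycodone,oral,6577450.3549242215
HIC_05,hydromorphone,oral,1884162.6236384804
HIC_05,morphine,parenteral,6400144.3273689514
HIC_05,fentanyl,transdermal,89722.489578974652
HIC_05,methadone,oral,414861.18604429066
HIC_06,morphine,oral,113194.31213552294
HIC_06,oxycodone,oral,2191358.3660297161
HIC_06,hydromorphone,oral,475761.87466865388
HIC_06,morphine,parenteral,1868173.9677417001
HIC_06,fentanyl,transdermal,99759.179587951861
HIC_06,methadone,oral,443689.96906559914
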