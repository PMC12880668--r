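t,glucose
0,151.26736601908107
5,148.29940790429794
10,146.71402230744738
15,141.72761442294407
20,147.89005735975638
25,153.14613422778589
30,146.47678995771241
35,150.43816659655258
40,141.55795057231006
45,150.98633115400841
50,148.55055364634597
55,122.73311741538970
60,130.59226610040548
65,134.12810939541859
70,157.89243101360933
75,153.21789827834994
80,161.88105449735292
85,147.89214349188308
90,160.95651028605141
95,168.14487965814229
100,146.56196914067669
105,149.73728134026987
110,147.71024022386365
115,152.28925435501361
120,175.02055793499727
125,147.97414620905897
130,167.28503158825973
135,149.70312218027070
140,169.67630833946325
145,158.74602019463052
150,168.62236095362840
155,170.79278150794528
160,179.84188236204935
165,163.69033961945746
170,172.00092261519660
175,169.02868783546211
180,172.77165413766957
185,175.92392936557130
190,157.08768355307464
195,177.64535535067716
200,190.06918094542448
205,180.33170352668517
210,185.70116289043119
215,171.69814379644845
220,171.91081432161357
225,165.78655618450645
230,166.31441601988840
235,188.03262693096491
240,173.31515769663966
245,187.59789647795407
250,189.96851958673565
255,176.32482241667560
260,179.57448782204142
265,176.72963442588295
270,178.92034265411257
275,189.72385559416108
280,187.60512975360120
285,200.66594662873308
290,194.35218617056162
295,199.83324581325269
300,184.88776678716513
305,195.73900027112512
310,185.03316532670365
315,181.49872888514724
320,194.22951281264159
325,180.19680485360888
330,188.82983767352385
335,197.42220989119619
340,190.97732223912317
345,197.49660774488129
350,181.51573093434786
355,202.26623039026742
360,200.42198121604429
365,194.09262272787649
370,186.35903882830203
375,193.83997489250379
380,194.22709271512798
385,192.90785805716399
390,183.45649273238601
395,204.20066679989708
400,199.80736098820427
405,200.47679929319744
410,188.32310968520690
415,199.71364526696485
420,194.61087739001533
425,193.31504617909104
430,196.92901049072537
435,183.70190524611618
440,188.41975217285074
445,204.67366766019720
450,191.96104154769966
455,198.06484828534619
460,207.17270600990625
465,226.41679185759159
470,236.86742856352924
475,268.35860786389992
480,287.48310444348567
485,321.28483919134612
490,325.19858073440321
495,340.75119597924299
500,335.92845526168628
505,355.20431769265849
510,342.70905479397720
515,366.11785201184279
520,360.98658401540592
525,357.39062255557502
530,335.98896919532564
535,327.99668602568886
540,343.03853078613696
545,318.37778411305987
550,297.02304281899410
555,303.11702155159833
560,300.92418782917747
565,292.21353075064593
570,292.42416382683393
575,267.58666443388415
580,265.39757953997372
585,267.67084205321743
590,273.64773863159547
595,258.66688474334330
600,246.26248635652516
605,246.83184509050560
610,245.20198027016971
615,233.63596469292716
620,240.15582474929496
625,236.65589887438861
630,237.12426918276174
635,218.73757226372905
640,222.80187864892756
645,207.21854803727308
650,235.71230842749043
655,205.70654921902309
660,218.54028806796376
665,207.79872934475102
670,205.36284986439185
675,201.21628032431852
680,207.41217808507031
685,211.15561176080220
690,198.76536303346950
695,187.68158697210006
700,200.31053661123241
705,193.94268219595963
710,201.91503975308990
715,199.39027511163331
720,189.63566968813757
725,188.84615054177846
730,198.32752958774648
735,210.49072119094248
740,208.45477227144369
745,190.70626541347471
750,187.82326184580640
755,193.83284565984997
760,190.63216789636479
765,184.84810350538282
770,192.42580018336486
775,201.27710221009727
780,182.37435536318679
785,199.12060526017177
790,197.11505151293352
795,181.52120208858611
800,201.87642882543886
805,190.80660889077919
810,182.35364224851818
815,206.88016074791858
820,192.64670654839995
825,215.98022859528200
830,194.97092731191512
835,194.18331983206005
840,207.67688208587890
845,199.57819174393953
850,197.20222382925138
855,195.49671011642374
860,196.47699675156409
865,183.96275208333267
870,188.72630790532966
875,192.68263919399729
880,191.17284206526807
885,186.38005740871589
890,188.67422606976010
895,180.84475644812153
900,189.87563279979977
905,203.44993976017187
910,187.78345984620771
915,187.58136393688235
920,190.23372131100902
925,192.65356945194307
930,172.84311706969743
935,176.98704010862616
940,177.35855674174945
945,193.92577987351055
950,197.77013725541070
955,198.51730774597462
960,191.88360876796747
965,171.18413914526343
970,189.52283213987667
975,180.81122130315060
980,197.47755383301072
985,201.09460432671452
990,191.21394542044123
995,180.88124308065028
1000,184.81524903735718
1005,183.87295487604135
1010,201.42030284933819
1015,189.86371062912616
1020,197.32220737298246
1025,200.11528559617904
1030,196.00435520027733
1035,188.63251625148186
1040,187.03305822717635
1045,192.69292520290549
1050,207.15429667467899
1055,185.11960930068216
1060,210.30848253606226
1065,192.63103216820454
1070,184.14782420010994
1075,190.88713009838045
1080,192.27361746630726
1085,199.94556815969230
1090,196.45342858840812
1095,191.77067484070125
1100,192.98509265519695
1105,195.39641926435237
1110,200.32485321365434
1115,209.54705351263624
1120,189.61040674954239
1125,198.00998334073398
1130,199.21347578019558
1135,190.34415519278349
1140,205.71592046318429
1145,193.33678272387593
1150,206.40704617019233
1155,227.42306587723829
1160,253.32594092505755
1165,281.59007251296782
1170,298.87241978440989
1175,320.49619001484751
1180,319.10114968836353
1185,363.86417641643339
1190,369.10769581431856
1195,374.57822894109489
1200,369.89630685384037
1205,368.49218802783321
1210,365.83232762720849
1215,352.76272494634429
1220,361.92215900425867
1225,352.75646362339518
1230,333.43841940999590
1235,323.55914356313787
1240,315.62138156933526
1245,318.50174521061473
1250,295.87734375665821
1255,288.42744007872619
1260,274.07183868065925
1265,269.05238077423832
1270,272.53910054824246
1275,253.64011472402552
1280,249.57715868785127
1285,249.92903661523243
1290,226.54313812263305
1295,223.42225341594968
1300,233.66473141096805
1305,223.39629121477441
1310,220.99856605712046
1315,228.82315407582126
1320,211.03184561596404
1325,200.32890799859015
1330,193.77106779881206
1335,194.36339062372906
1340,199.10776356593504
1345,193.62675979378724
1350,182.95215027382736
1355,187.57862005014229
1360,170.34360327542137
1365,178.72789410483705
1370,177.86240621002923
1375,184.75979607487469
1380,159.44385439863848
1385,178.25465715817757
1390,171.46833759737567
1395,159.11151003655561
1400,169.50514019786513
1405,174.17166422040793
1410,161.90922869685096
1415,178.42456683711171
1420,165.88644504173769
1425,169.20658526797467
1430,163.26988647041372
1435,162.17835013142923
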