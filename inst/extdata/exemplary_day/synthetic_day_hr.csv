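t,bpm
0,68
5,70
10,69
20,67
25,63
30,67
35,71
40,64
45,66
50,68
55,66
65,66
70,64
75,62
80,62
85,68
90,66
95,64
100,66
105,66
115,67
125,67
130,71
140,62
145,60
155,71
165,63
170,67
185,62
190,63
195,67
205,63
210,62
215,64
220,69
225,65
230,64
235,65
240,67
245,63
255,66
260,65
270,67
275,62
280,67
290,66
295,63
305,68
310,61
325,62
330,64
335,65
340,64
345,67
355,66
365,61
370,71
375,68
385,60
390,67
400,68
415,63
420,61
425,64
430,67
445,66
450,70
455,67
465,63
470,64
475,63
480,60
485,61
490,68
495,65
500,66
505,70
515,61
525,64
530,63
535,75
540,59
550,68
560,66
565,61
570,67
575,70
580,65
585,65
590,64
595,67
605,64
615,70
620,69
625,66
630,64
635,59
645,68
650,60
655,66
660,68
665,67
670,71
675,64
685,67
690,69
700,66
705,64
710,66
715,67
720,65
725,67
735,59
740,61
745,71
750,70
760,68
765,68
775,63
780,62
785,67
790,59
800,63
805,69
820,123
825,121
835,119
840,117
845,65
850,69
855,65
860,65
865,67
870,69
880,64
890,68
900,64
905,70
910,61
915,63
920,65
925,64
930,65
940,68
945,68
950,58
955,65
960,65
965,63
970,64
975,68
980,68
990,62
995,65
1005,65
1010,64
1015,67
1020,72
1025,63
1030,74
1035,64
1045,64
1050,68
1055,59
1060,66
1065,63
1070,71
1080,63
1090,66
1095,63
1105,68
1120,70
1140,75
1145,65
1150,71
1155,68
1160,68
1165,69
1175,68
1180,68
1185,60
1190,69
1195,60
1200,66
1205,70
1215,64
1220,68
1225,66
1240,65
1245,69
1255,68
1260,66
1265,63
1270,68
1275,60
1280,67
1285,67
1295,68
1300,66
1305,62
1310,64
1315,63
1320,73
1325,58
1330,67
1340,68
1350,64
1355,62
1365,65
1380,64
1385,65
1390,58
1395,65
1400,67
1405,63
1415,69
1420,61
1425,62
1430,69
1435,65
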