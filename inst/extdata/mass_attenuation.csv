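energy_kev,water,hydroxyapatite
30,0.3786492104,2.1316863611
35,0.3094701899,1.4040482808
40,0.2693597430,0.9944518728
45,0.2440362982,0.7460501585
50,0.2269000000,0.5864000000
55,0.2146117324,0.4788827474
60,0.2053568421,0.4036257108
65,0.1980901271,0.3492062156
70,0.1921797498,0.3087391981
75,0.1872277645,0.2779054783
80,0.1829745065,0.2539015161
85,0.1792452078,0.2348531235
90,0.1759189598,0.2194747151
95,0.1729100235,0.2068642064
100,0.1701562225,0.1963757093
105,0.1676115330,0.1875383378
110,0.1652412382,0.1800031530
115,0.1630186869,0.1735077337
120,0.1609230831,0.1678520481
125,0.1589379499,0.1628817269
130,0.1570500445,0.1584762783
135,0.1552485803,0.1545406595
140,0.1535246597,0.1509991674
145,0.1518708574,0.1477909529
150,0.1502809079,0.1448666892
155,0.1487494700,0.1421860709
160,0.1472719470,0.1397159161
165,0.1458443480,0.1374287147
170,0.1444631791,0.1353015059
175,0.1431253591,0.1333150051
180,0.1418281508,0.1314529176
185,0.1405691079,0.1297013967
190,0.1393460305,0.1280486117
195,0.1381569301,0.1264844025
200,0.1370000000,0.1250000000
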