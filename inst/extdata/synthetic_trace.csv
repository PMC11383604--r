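"time_s","displacement_um","force_nN","phase"
0,0.357018581183849,110,"on"
0.5,0.407378814573905,110,"on"
1,0.47181058148926,110,"on"
1.5,0.493072636506089,110,"on"
2,0.513620633245666,110,"on"
2.5,0.542983509081588,110,"on"
3,0.575568690873889,110,"on"
3.5,0.572402660791551,110,"on"
4,0.577825915634585,110,"on"
4.5,0.586446765495399,110,"on"
5,0.607171731932112,110,"on"
5.5,0.646630407367176,110,"on"
6,0.638364490889895,110,"on"
6.5,0.642044588392681,110,"on"
7,0.667934038021324,110,"on"
7.5,0.666785157607213,110,"on"
8,0.704786490513585,110,"on"
8.5,0.713631948784407,110,"on"
9,0.698624061374417,110,"on"
9.5,0.708120000201613,110,"on"
10,0.364923636323914,0,"off"
10.5,0.33609730715702,0,"off"
11,0.294129368721214,0,"off"
11.5,0.278458340158064,0,"off"
12,0.258633618905143,0,"off"
12.5,0.244855072067995,0,"off"
13,0.230194070641104,0,"off"
13.5,0.196890642262963,0,"off"
14,0.208594955475742,0,"off"
14.5,0.207944597136911,0,"off"
15,0.189728574642546,0,"off"
15.5,0.199658182616491,0,"off"
16,0.176338935337296,0,"off"
16.5,0.191855686233239,0,"off"
17,0.194230840276806,0,"off"
17.5,0.177279196943961,0,"off"
18,0.198394458942681,0,"off"
18.5,0.181875643467576,0,"off"
19,0.171045174479796,0,"off"
19.5,0.18508360765248,0,"off"
20,0.170543683892074,0,"off"
20.5,0.175914635461105,0,"off"
21,0.182610441843688,0,"off"
21.5,0.174715634414203,0,"off"
22,0.178692036239349,0,"off"
22.5,0.177947937772437,0,"off"
23,0.18262479207761,0,"off"
23.5,0.193457813616187,0,"off"
24,0.18717230003851,0,"off"
24.5,0.181323062097169,0,"off"
25,0.186260630174752,0,"off"
25.5,0.178424375288432,0,"off"
26,0.197178834759053,0,"off"
26.5,0.174300988164108,0,"off"
27,0.187410897056979,0,"off"
27.5,0.18867250711439,0,"off"
28,0.203814240151293,0,"off"
28.5,0.173201442121401,0,"off"
29,0.169337564418664,0,"off"
29.5,0.199083276151835,0,"off"
30,0.546823366914126,110,"on"
30.5,0.586357443770325,110,"on"
31,0.657620221326382,110,"on"
31.5,0.67581015284512,110,"on"
32,0.688927436624791,110,"on"
32.5,0.725433613044194,110,"on"
33,0.74492092431514,110,"on"
33.5,0.762169330215291,110,"on"
34,0.765299735559527,110,"on"
34.5,0.797150273337922,110,"on"
35,0.811919680641068,110,"on"
35.5,0.821184532129523,110,"on"
36,0.809750853066683,110,"on"
36.5,0.867433291917808,110,"on"
37,0.84524549896102,110,"on"
37.5,0.863054156636402,110,"on"
38,0.883821440817048,110,"on"
38.5,0.908882687893706,110,"on"
39,0.907648948751688,110,"on"
39.5,0.898945189397713,110,"on"
40,0.541972044748974,0,"off"
40.5,0.513969782299659,0,"off"
41,0.479983577794878,0,"off"
41.5,0.435810496490264,0,"off"
42,0.441864003856032,0,"off"
42.5,0.413936025192682,0,"off"
43,0.411445417772266,0,"off"
43.5,0.391352427225699,0,"off"
44,0.405012406438117,0,"off"
44.5,0.386992112729962,0,"off"
45,0.385777298570356,0,"off"
45.5,0.377415063665041,0,"off"
46,0.371526553194478,0,"off"
46.5,0.379786401163843,0,"off"
47,0.37526388595688,0,"off"
47.5,0.359948610606613,0,"off"
48,0.363577068466385,0,"off"
48.5,0.370957730462418,0,"off"
49,0.375231447623165,0,"off"
49.5,0.354052219616759,0,"off"
50,0.353366349404546,0,"off"
50.5,0.35615115531003,0,"off"
51,0.364464788583923,0,"off"
51.5,0.381530021920326,0,"off"
52,0.353490536044245,0,"off"
52.5,0.357820100475473,0,"off"
53,0.376635170714195,0,"off"
53.5,0.344478956863013,0,"off"
54,0.360495909136974,0,"off"
54.5,0.372654264559072,0,"off"
55,0.368027843362302,0,"off"
55.5,0.362717967810183,0,"off"
56,0.355579467772728,0,"off"
56.5,0.385244256146304,0,"off"
57,0.360448593082722,0,"off"
57.5,0.352709482033351,0,"off"
58,0.369783961306165,0,"off"
58.5,0.36577516616843,0,"off"
59,0.373307007431,0,"off"
59.5,0.359822545657169,0,"off"
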