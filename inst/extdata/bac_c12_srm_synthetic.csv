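scan,time_min,mz,intensity
0,0,212.075930628284,273.485288149338
0,0,212.262058907292,708.682344734943
1,0.01,212.102030923765,733.386391971905
1,0.01,212.109769657772,398.669488140572
2,0.02,211.824718454452,335.63147339329
2,0.02,212.223923811502,704.096910986266
3,0.03,211.924541860674,380.841020457545
3,0.03,212.201525121505,696.703424952632
4,0.04,211.529181093147,332.935652508479
4,0.04,212.143336038472,581.248237260057
5,0.05,211.86032719102,356.804277565519
5,0.05,211.958391096799,698.181733461392
6,0.06,211.70837784902,406.759308863722
6,0.06,212.136485320254,576.005641464254
7,0.07,211.765187876929,359.485154044711
7,0.07,212.107987773686,812.219278144243
8,0.08,211.872824984386,342.514069789489
8,0.08,212.22135544413,639.73444115264
9,0.09,211.944999531741,279.518703443709
9,0.09,212.162620901816,731.856803543403
10,0.1,211.783073179282,354.828834397776
10,0.1,212.169178529566,761.559734459934
11,0.11,212.136956672141,720.434903558061
11,0.11,212.185806096889,295.146240066403
12,0.12,211.878350862384,450.830239123545
12,0.12,212.187856340059,827.761666772315
13,0.13,211.759643399866,340.571458619015
13,0.13,212.187418347557,652.23732661632
14,0.14,211.8562340207,272.118520285571
14,0.14,211.955311855387,755.471841385262
15,0.15,211.774961344688,418.462169975219
15,0.15,212.34470014993,641.828042534135
16,0.16,211.625989401201,292.399693300925
16,0.16,212.271640814585,889.959290841089
17,0.17,211.865487100787,224.811740683629
17,0.17,212.231756433831,775.015916844923
18,0.18,211.932386013668,257.305059555693
18,0.18,212.12952811696,692.530542385568
19,0.19,211.847420308403,322.499219953146
19,0.19,212.278974677763,782.813557813916
20,0.2,211.845736731635,294.07841735136
20,0.2,212.177132798591,627.553803138359
21,0.21,211.813582460248,347.515468861208
21,0.21,212.193531842307,840.713307711416
22,0.22,211.917190983496,306.238880836441
22,0.22,212.070797112023,627.560307179412
23,0.23,211.597491101524,208.58226740955
23,0.23,212.35658247612,595.455055183465
24,0.24,211.963741791213,302.619549621131
24,0.24,212.214820680823,715.580165982115
25,0.25,211.653634068025,426.028474272151
25,0.25,212.400808383464,787.935453016217
26,0.26,211.840248605775,293.439026161951
26,0.26,212.383094452724,719.112262199707
27,0.27,211.906378112287,284.668135879906
27,0.27,212.215814583726,659.174893457543
28,0.28,211.825571022841,312.764704498826
28,0.28,212.274532816178,814.063940134099
29,0.29,211.556019479812,419.183676911708
29,0.29,212.382562898651,913.155976722781
30,0.3,211.793649012678,267.718725882215
30,0.3,212.157103308254,563.318978541909
31,0.31,211.840195278374,366.840096251467
31,0.31,212.226639202561,837.887191474384
32,0.32,211.938411649872,283.16732784088
32,0.32,212.184527642524,682.009283080102
33,0.33,211.865056267031,300.344521321637
33,0.33,212.243278235944,798.49367870287
34,0.34,211.876536179818,298.687039045907
34,0.34,212.228243281283,574.051582437075
35,0.35,211.961403641018,366.85604446201
35,0.35,212.326459374952,699.151134611819
36,0.36,211.683882827837,356.520210307126
36,0.36,212.269349285073,643.292374994107
37,0.37,211.697216053853,384.570741048409
37,0.37,212.120822027078,680.776343194678
38,0.38,211.788752870579,383.933459138793
38,0.38,212.267725331036,633.816262911947
39,0.39,211.840837960093,449.698784769756
39,0.39,212.127509441894,749.554072843556
40,0.4,212.000810944827,324.227388923137
40,0.4,212.094274614238,817.301318491148
41,0.41,211.660209522146,167.88648682441
41,0.41,212.287799877401,680.492541150872
42,0.42,211.658906906507,287.519951316597
42,0.42,212.089577821403,701.777222321825
43,0.43,211.906147730124,273.443625587531
43,0.43,212.240671410215,631.068089036218
44,0.44,211.729716463772,302.242674905614
44,0.44,212.126634145936,799.66664715277
45,0.45,211.75772932542,389.082374325403
45,0.45,212.35181411635,764.946311275687
46,0.46,211.880788419577,285.866727948109
46,0.46,212.281178611785,594.85771547873
47,0.47,211.697814847453,271.652819598498
47,0.47,212.169750227714,838.486161528425
48,0.48,211.681336560286,349.555631710498
48,0.48,212.289936221871,626.463587991021
49,0.49,211.751458604423,362.045500239935
49,0.49,212.252648443556,635.838917002692
50,0.5,211.731189089548,305.412482506995
50,0.5,212.093010133006,602.252358013678
51,0.51,211.686994705738,344.748870615349
51,0.51,212.189379983971,624.525046338865
52,0.52,211.92137605102,349.889918561528
52,0.52,212.116938969076,692.161646024645
53,0.53,211.717841302094,342.060746877382
53,0.53,212.254939756579,762.625803451954
54,0.54,211.80025363863,285.763827848618
54,0.54,212.145519354544,663.120913931933
55,0.55,211.810553733922,364.328991062862
55,0.55,212.186857731019,704.080868989408
56,0.56,211.511184722169,183.902520460103
56,0.56,212.086363198855,697.490134118523
57,0.57,211.841941485704,356.842462403148
57,0.57,212.113904470178,813.674102016398
58,0.58,212.015245072992,344.218148359995
58,0.58,212.223395628157,903.0986548736
59,0.59,211.787939281951,443.094759601959
59,0.59,212.110094727703,634.491470840074
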