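position	token	value
1	AC	0.1600396892221179
1	AG	0.2239022158824373
1	AT	0.34413916464778593
1	CA	0.5450164662068709
1	CG	0.12180747669143602
1	CT	0.5391354212956503
1	GA	0.5668604858946055
1	GC	0.396817877699621
1	GT	0.3778393122954294
1	TA	0.03800997601007111
1	TC	0.12437877036468126
1	TG	0.10675749476486816
2	AC	0.4125266851480119
2	AG	0.23107812721002846
2	AT	0.46213501057913525
2	CA	0.29912184600904584
2	CG	0.430853486450389
2	CT	0.5951517508034594
2	GA	0.22864107248117216
2	GC	0.46668968757055695
2	GT	0.5608884334324393
2	TA	0.1280733702483121
2	TC	0.3913525858854409
2	TG	0.07620750248082914
3	AC	0.16106518056779168
3	AG	0.23228234143368898
3	AT	0.00902080956217833
3	CA	0.23005038628494368
3	CG	0.5219448165865614
3	CT	0.2048690490159206
3	GA	0.2897659891671501
3	GC	0.36013992942962797
3	GT	0.2966312429222744
3	TA	0.11254434324521571
3	TC	0.49659661784558556
3	TG	0.4014115761772264
4	AC	0.4767496765751857
4	AG	0.06565823190682568
4	AT	0.43450285667809657
4	CA	0.24735338335647247
4	CG	0.4927468301753979
4	CT	0.38858905609813515
4	GA	0.4699767246113624
4	GC	0.3322687506731599
4	GT	0.3183020285384264
4	TA	0.4738243827819824
4	TC	0.014975390197942032
4	TG	0.28686080895690247
5	AC	0.43965592946344983
5	AG	0.4159462023330852
5	AT	0.2870941536591854
5	CA	0.516864476622548
5	CG	0.2634201672272757
5	CT	0.14763356894184834
5	GA	0.04333674923982471
5	GC	0.06058022994338535
5	GT	0.1904467526024673
5	TA	0.31166192365274764
5	TC	0.39754104077420194
5	TG	0.2446912821258884
6	AC	0.547812678631395
6	AG	0.1768684202833101
6	AT	0.27598037002957426
6	CA	0.20010440983832814
6	CG	0.39087140977522356
6	CT	0.15555205164966174
6	GA	0.287648603717098
6	GC	0.4600200917168986
6	GT	0.05146390170650557
6	TA	0.5253174766921438
6	TC	0.20410468976874835
6	TG	0.5038247697625775
7	AC	0.20866341000609098
7	AG	0.20093118354771286
7	AT	0.28633439579908737
7	CA	0.535426803171169
7	CG	0.5187393429076764
7	CT	0.23460373654053546
7	GA	0.46661509860213846
7	GC	0.5764101803335361
7	GT	0.2613610313795507
7	TA	0.4277962925501633
7	TC	0.2405966269697528
7	TG	0.19588593897502868
8	AC	0.45449520166846924
8	AG	0.12241266083181836
8	AT	0.42696161225950346
8	CA	0.07389346069539897
8	CG	0.14804761986178344
8	CT	0.08683932327502407
8	GA	0.14453801964293234
8	GC	0.036301691986853256
8	GT	0.38573066686070523
8	TA	0.5258852584019769
8	TC	0.4675698917894624
8	TG	0.47858798670675606
9	AC	0.2737093977180775
9	AG	0.24664036514586768
9	AT	0.48671127541968595
9	CA	0.3633550408757292
9	CG	0.3931796329182107
9	CT	0.2125651658894494
9	GA	0.16288582738675175
9	GC	0.5956177526428365
9	GT	0.3804624653987121
9	TA	0.1287116729952395
9	TC	0.07849403649847954
9	TG	0.28739270255318844
10	AC	0.5545206074297894
10	AG	0.3596578193185851
10	AT	0.5857262462577782
10	CA	0.43934371461858973
10	CG	0.21467942033777945
10	CT	0.2594527406399138
10	GA	0.08977872484596446
10	GC	0.00883346771285869
10	GT	0.4296240735901519
10	TA	0.06280735721299424
10	TC	0.26832432481786234
10	TG	0.3844205260372255
11	AC	0.9918467814242468
11	AG	0.49609798427834173
11	AT	0.48486517484509384
11	CA	0.17426889253314584
11	CG	0.7550661235640291
11	CT	0.45444159373035653
11	GA	0.511658613987267
11	GC	0.2083375681708567
11	GT	0.22942948458972387
11	TA	0.5961162843168714
11	TC	0.5752973260835279
11	TG	0.07798731590225362
12	AC	0.03650503900577314
12	AG	0.6431526967042591
12	AT	0.9286865844351705
12	CA	0.5984943299326114
12	CG	0.5613398472608533
12	CT	0.5265016961900983
12	GA	0.9851101286537014
12	GC	0.5081341805101838
12	GT	0.68310529059451075
12	TA	0.6019396764317062
12	TC	0.23962980907806194
12	TG	0.25890776074584576
13	AC	0.729580313739134
13	AG	0.4531182605717331
13	AT	0.17595164164737798
13	CA	0.7469515713509172
13	CG	0.10588265275908634
13	CT	0.8646804040796123
13	GA	0.6150303267044946
13	GC	0.5576023793076165
13	GT	0.3294485417341348
13	TA	0.45367831400525754
13	TC	0.5009405316517223
13	TG	0.18168549476889895
14	AC	0.5301009722002782
14	AG	0.07620046996278688
14	AT	0.2784781767169479
14	CA	0.2134868197182659
14	CG	0.2855056904940866
14	CT	0.8951990088440943
14	GA	0.44678908800147477
14	GC	0.780204904895043
14	GT	0.8807384158347268
14	TA	0.41371108529320916
14	TC	0.06474467202997766
14	TG	0.3361520041923504
15	AC	0.7240022206734866
15	AG	0.33827771816402674
15	AT	0.630783708360279
15	CA	0.8407739394525997
15	CG	0.8562755330454093
15	CT	0.3919679217466619
15	GA	0.38111339171906
15	GC	0.8955499805686995
15	GT	0.6446714471480809
15	TA	0.7413375700674951
15	TC	0.6056981430829037
15	TG	0.9031785298858304
16	AC	0.2944364249440841
16	AG	0.1920688497785013
16	AT	0.8865644923609216
16	CA	0.5038361462452449
16	CG	0.8771804854813963
16	CT	0.1900044288195204
16	GA	0.758344949334627
16	GC	0.724774393775966
16	GT	0.943781093476573
16	TA	0.5480989404290448
16	TC	0.7120321238555479
16	TG	0.38951619472610766
17	AC	0.10177225305652246
17	AG	0.9273747864998877
17	AT	0.28394926781067625
17	CA	0.5909825856548269
17	CG	0.11125024433876388
17	CT	0.8406665250847581
17	GA	0.31864572075894104
17	GC	0.7830684856525623
17	GT	0.2682406991473399
17	TA	0.21942663959879427
17	TC	0.5172800395602826
17	TG	0.26968164143594914
18	AC	0.18198715901351534
18	AG	0.5190575613512192
18	AT	0.56322015286237
18	CA	0.1300276976148598
18	CG	0.2571112364113797
18	CT	0.718217340708943
18	GA	0.9614485264897812
18	GC	0.1010407057206612
18	GT	0.7634594668180216
18	TA	0.9480183883116114
18	TC	0.8188160537001676
18	TG	0.3089840383776464
19	AC	0.6499298810393084
19	AG	0.9534020956633612
19	AT	0.9537789173785132
19	CA	0.34063922421447934
19	CG	0.26321163600706493
19	CT	0.16628847924619913
19	GA	0.32284588856366464
19	GC	0.5106150813440327
19	GT	0.9240445028825197
19	TA	0.5114487386546098
19	TC	0.258363639564719
19	TG	0.0474144260645844
20	AC	0.41843840208183974
20	AG	0.8541475007713306
20	AT	0.3478834470480215
20	CA	0.13231087821256368
20	CG	0.3751123776799068
20	CT	0.6317888081690762
20	GA	0.39068885474302806
20	GC	0.6899382209496107
20	GT	0.6897239990616217
20	TA	0.5553457225363236
20	TC	0.43019478337722833
20	TG	0.4532673427443951
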