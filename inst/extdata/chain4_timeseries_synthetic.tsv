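metabolite	time	value
A	0	0.96867730946288333
A	0	1.009182166211104
A	0	0.95821856937949768
A	54.545454545454547	0.36270459833439322
A	54.545454545454547	0.34144524529554982
A	54.545454545454547	0.32213076434234755
A	109.09090909090909	0.11558616900144059
A	109.09090909090909	0.11700167444336698
A	109.09090909090909	0.11608463583023368
A	163.63636363636363	0.037324158778926142
A	163.63636363636363	0.040767959873103748
A	163.63636363636363	0.038641724010283755
A	218.18181818181819	0.012336523178150203
A	218.18181818181819	0.011322126578024599
A	218.18181818181819	0.013448136398598242
A	272.72727272727275	0.0042672116620234369
A	272.72727272727275	0.0042733581683039156
A	272.72727272727275	0.0044786512043939446
A	327.27272727272725	0.0014956204903758346
A	327.27272727272725	0.001479291752591449
A	327.27272727272725	0.0015026424675826165
A	381.81818181818181	0.00050145227054981291
A	381.81818181818181	0.0004843792787007238
A	381.81818181818181	0.00043457902284404435
A	436.36363636363637	0.00016712778209383212
A	436.36363636363637	0.00016164903675132929
A	436.36363636363637	0.00016084121781288153
A	490.90909090909093	5.0448202585328398e-05
A	490.90909090909093	5.3150687025440672e-05
A	490.90909090909093	5.559040893324265e-05
A	545.4545454545455	1.9649878165531088e-05
A	545.4545454545455	1.8188410886659047e-05
A	545.4545454545455	1.8678870225561414e-05
A	600	6.090404678151433e-06
A	600	4.7671501619057313e-06
A	600	5.7292151554346585e-06
B	0	0
B	0	0
B	0	1.1000253719838831e-06
B	54.545454545454547	0.5059306920808857
B	54.545454545454547	0.48332569286502369
B	54.545454545454547	0.4811609992841121
B	109.09090909090909	0.46169708419225186
B	109.09090909090909	0.45856734088964862
B	109.09090909090909	0.43078518458152121
B	163.63636363636363	0.30247521061564497
B	163.63636363636363	0.31928364244105883
B	163.63636363636363	0.325616938890532
B	218.18181818181819	0.19908373188084252
B	218.18181818181819	0.20902862129107183
B	218.18181818181819	0.20419357080949554
B	272.72727272727275	0.11850042484359703
B	272.72727272727275	0.12432610927369668
B	272.72727272727275	0.11533843275943191
B	327.27272727272725	0.078158271849914931
B	327.27272727272725	0.080154349407121586
B	327.27272727272725	0.071593446746840428
B	381.81818181818181	0.040726915200820328
B	381.81818181818181	0.044194301365662651
B	381.81818181818181	0.042680085064323345
B	436.36363636363637	0.028158612202100548
B	436.36363636363637	0.025090478108826243
B	436.36363636363637	0.026006797968713257
B	490.90909090909093	0.014669993133258298
B	490.90909090909093	0.014105053891801906
B	490.90909090909093	0.014787767749106565
B	545.4545454545455	0.007748411421521351
B	545.4545454545455	0.0091411691276901894
B	545.4545454545455	0.0085823216975239487
B	600	0.0054824175997543467
B	600	0.0050627907742247418
B	600	0.0047696739905782621
C	0	6.1072635348905493e-07
C	0	0
C	0	0
C	54.545454545454547	0.16202979332257339
C	54.545454545454547	0.15616281555652756
C	54.545454545454547	0.15971138423220646
C	109.09090909090909	0.35365609632928591
C	109.09090909090909	0.34196062222941181
C	109.09090909090909	0.34232798234653977
C	163.63636363636363	0.44538137962277036
C	163.63636363636363	0.47482559352313175
C	163.63636363636363	0.41425287192351201
C	218.18181818181819	0.47509603079154583
C	218.18181818181819	0.46907493724773486
C	218.18181818181819	0.48591926179100353
C	272.72727272727275	0.41957725244530741
C	272.72727272727275	0.4339397002584609
C	272.72727272727275	0.43174720929049842
C	327.27272727272725	0.35944620527295862
C	327.27272727272725	0.39178185545780669
C	327.27272727272725	0.3909050110484158
C	381.81818181818181	0.318796531585119
C	381.81818181818181	0.33245104372990242
C	381.81818181818181	0.31661384167711371
C	436.36363636363637	0.23421543078096713
C	436.36363636363637	0.24301350802856722
C	436.36363636363637	0.23486565551745447
C	490.90909090909093	0.19490323841813945
C	490.90909090909093	0.19343630827054262
C	490.90909090909093	0.20004882651082856
C	545.4545454545455	0.15014531959643965
C	545.4545454545455	0.15855315886622265
C	545.4545454545455	0.15216154064056309
C	600	0.13371503001879537
C	600	0.12726138667466952
C	600	0.12844984035880644
D	0	3.8418535782634458e-07
D	0	1.6821760805194182e-06
D	0	0
D	54.545454545454547	0.016658270722253312
D	54.545454545454547	0.018273020159488423
D	54.545454545454547	0.016497086575884924
D	109.09090909090909	0.087748423354311489
D	109.09090909090909	0.086926352106756477
D	109.09090909090909	0.087249169754440248
D	163.63636363636363	0.19732456074341798
D	163.63636363636363	0.20506211370661573
D	163.63636363636363	0.19834298606555409
D	218.18181818181819	0.31742710531853152
D	218.18181818181819	0.3475348440329018
D	218.18181818181819	0.32217169802768825
D	272.72727272727275	0.44340787126485864
D	272.72727272727275	0.44518338226841575
D	272.72727272727275	0.4633680012937233
D	327.27272727272725	0.55411670851764983
D	327.27272727272725	0.55511586073238695
D	327.27272727272725	0.53720670001588433
D	381.81818181818181	0.63801935393160314
D	381.81818181818181	0.65048518052761084
D	381.81818181818181	0.62943845897138717
D	436.36363636363637	0.74376728388269375
D	436.36363636363637	0.66950862745757012
D	436.36363636363637	0.73561874124624127
D	490.90909090909093	0.72531067160269114
D	490.90909090909093	0.77384425523841083
D	490.90909090909093	0.76491499439641153
D	545.4545454545455	0.80695707961172802
D	545.4545454545455	0.83178143329306398
D	545.4545454545455	0.75431089491735259
D	600	0.92350014707061878
D	600	0.79958133010494881
D	600	0.85197561295175517
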