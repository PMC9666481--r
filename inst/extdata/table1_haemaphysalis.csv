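species,name,feature_class,strand,start,end,length_printed,start_codon,stop_codon,anticodon,intergenic_printed,note
nepalensis,trnC,tRNA,N,1,55,55,,,GCA,2,
nepalensis,trnM,tRNA,N,58,122,65,,,ATG,,printed anticodon equals the codon not the anticodon triplet
nepalensis,nad2,PCG,N,123,1082,960,ATT,TAA,,-2,
nepalensis,trnW,tRNA,N,1081,1141,61,,,TCA,-2,
nepalensis,trnY,tRNA,J,1140,1203,64,,,GTA,7,
nepalensis,cox1,PCG,N,1211,2734,1524,ATA,TAA,,4,
nepalensis,cox2,PCG,N,2739,3414,676,ATG,T(AA),,,
nepalensis,trnK,tRNA,N,3415,3481,67,,,CTT,-1,
nepalensis,trnD,tRNA,N,3481,3547,67,,,GTC,,
nepalensis,atp8,PCG,N,3548,3706,159,ATC,TAA,,-7,
nepalensis,atp6,PCG,N,3700,4365,666,ATG,TAA,,3,
nepalensis,cox3,PCG,N,4369,5146,778,ATG,T(AA),,0,
nepalensis,trnG,tRNA,N,5147,5207,61,,,TCC,-3,
nepalensis,nad3,PCG,N,5205,5546,342,ATA,TAG,,-2,
nepalensis,trnA,tRNA,N,5545,5605,61,,,TGC,4,
nepalensis,trnR,tRNA,N,5610,5669,60,,,TCG,-2,
nepalensis,trnN,tRNA,N,5668,5728,61,,,GTT,19,
nepalensis,trnS1,tRNA,N,5748,5802,55,,,TCT,4,
nepalensis,trnE,tRNA,N,5807,5867,61,,,TTC,-7,
nepalensis,nad1,PCG,J,5861,6802,942,ATT,TAA,,,
nepalensis,trnL2,tRNA,J,6803,6863,61,,,TAA,-41,
nepalensis,rrnL,rRNA,J,6823,8065,1243,,,,-10,printed rRNA lengths differ wildly between the two species; looks like an annotation gap
nepalensis,trnV,tRNA,J,8056,8117,62,,,TAC,-9,
nepalensis,rrnS,rRNA,J,8109,8793,685,,,,334,printed rRNA lengths differ wildly between the two species; looks like an annotation gap
nepalensis,trnI,tRNA,N,9128,9192,65,,,GAT,,
nepalensis,trnQ,tRNA,J,9193,9259,67,,,TTG,13,
nepalensis,trnF,tRNA,J,9273,9333,61,,,GAA,-1,
nepalensis,nad5,PCG,J,9333,10988,1656,ATT,TAA,,,
nepalensis,trnH,tRNA,J,10989,11052,64,,,GTG,0,
nepalensis,nad4,PCG,J,11053,12367,1315,ATG,T(AA),,-7,
nepalensis,nad4l,PCG,J,12361,12636,276,ATG,TAA,,2,
nepalensis,trnT,tRNA,N,12639,12701,63,,,TGT,0,
nepalensis,trnP,tRNA,J,12702,12761,60,,,TGG,3,
nepalensis,nad6,PCG,N,12765,13218,454,ATT,T(AA),,-21,
nepalensis,cytb,PCG,N,13198,14277,1080,ATG,TAG,,-1,
nepalensis,trnS2,tRNA,N,14277,14339,63,,,TGA,6,
nepalensis,trnL1,tRNA,J,14346,14411,66,,,TAG,56,
nepalensis,OH,control_region,N,14468,14712,245,,,,7,closure spacing from coordinates is 8 (L=14720); printed column says 7
yeni,trnC,tRNA,N,1,57,57,,,GCA,-1,
yeni,trnM,tRNA,N,57,119,63,,,ATG,,printed anticodon equals the codon not the anticodon triplet
yeni,nad2,PCG,N,120,1079,960,ATT,TAA,,5,
yeni,trnW,tRNA,N,1085,1148,64,,,TCA,1,
yeni,trnY,tRNA,J,1150,1213,64,,,GTA,-8,
yeni,cox1,PCG,N,1206,2744,1539,ATT,TAA,,4,
yeni,cox2,PCG,N,2749,3423,675,ATG,TAA,,,printed length 675 is not a codon multiple yet the printed stop is complete
yeni,trnK,tRNA,N,3424,3488,65,,,CTT,-1,
yeni,trnD,tRNA,N,3488,3552,65,,,GTC,,
yeni,atp8,PCG,N,3553,3714,162,ATT,TAA,,-7,
yeni,atp6,PCG,N,3708,4373,666,ATG,TAA,,3,
yeni,cox3,PCG,N,4377,5156,780,ATG,TAA,,-1,
yeni,trnG,tRNA,N,5156,5216,61,,,TCC,0,
yeni,nad3,PCG,N,5217,5558,342,ATT,TAA,,-1,
yeni,trnA,tRNA,N,5558,5619,62,,,TGC,3,
yeni,trnR,tRNA,N,5623,5682,60,,,TCG,-2,
yeni,trnN,tRNA,N,5681,5741,61,,,GTT,2,
yeni,trnS1,tRNA,N,5744,5800,57,,,TCT,14,
yeni,trnE,tRNA,N,5815,5875,61,,,TTC,184,
yeni,nad1,PCG,J,6060,7010,951,ATT,TA(A),,-13,
yeni,trnL2,tRNA,J,6998,7059,62,,,TAA,56,
yeni,rrnL,rRNA,J,7116,7704,589,,,,556,printed rRNA lengths differ wildly between the two species; looks like an annotation gap
yeni,trnV,tRNA,J,8261,8321,61,,,TAC,3,
yeni,rrnS,rRNA,J,8325,8744,420,,,,575,printed rRNA lengths differ wildly between the two species; looks like an annotation gap
yeni,trnI,tRNA,N,9320,9385,66,,,GAT,,
yeni,trnQ,tRNA,J,9386,9451,66,,,TTG,0,
yeni,trnF,tRNA,J,9452,9513,62,,,GAA,-3,
yeni,nad5,PCG,J,9511,11171,1661,ATT,TA(A),,,
yeni,trnH,tRNA,J,11172,11230,59,,,GTG,-1,
yeni,nad4,PCG,J,11230,12546,1317,ATG,TAG,,-7,
yeni,nad4l,PCG,J,12540,12815,276,ATG,TAA,,2,
yeni,trnT,tRNA,N,12818,12879,62,,,TGT,-1,
yeni,trnP,tRNA,J,12879,12942,64,,,TGG,1,
yeni,nad6,PCG,N,12944,13372,429,ATC,TAA,,3,
yeni,cytb,PCG,N,13376,14455,1080,ATG,TAG,,-2,
yeni,trnS2,tRNA,N,14454,14515,62,,,TGA,-1,
yeni,trnL1,tRNA,J,14515,14579,65,,,TAG,315,
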