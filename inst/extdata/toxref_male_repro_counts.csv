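level,category,subendpoint,rabbit,rabbit_mean_clel,mouse,mouse_mean_clel,rat,rat_mean_clel,p1,p1_mean_clel,f1,f1_mean_clel,p1_or_f1,mrdt
category,malformation,,1,,0,,14,,NA,,12,,12,12
subendpoint,malformation,hypospadias,0,,0,,2,98,NA,,2,98,2,2
subendpoint,malformation,nipple retention,0,,0,,3,70,NA,,3,70,3,3
subendpoint,malformation,decreased anogenital distance,0,,0,,9,57,NA,,8,232,8,8
subendpoint,malformation,cryptorchidism,1,80,0,,7,241,NA,,6,285,6,6
category,tumor,,0,,1,,27,,28,,NA,,28,NA
subendpoint,tumor,mesothelioma,0,,0,,5,6,5,6,NA,,5,NA
subendpoint,tumor,adenoma,0,,0,,8,25,8,25,NA,,8,NA
subendpoint,tumor,interstitial cell tumor,0,,1,113,15,35,16,38,NA,,16,NA
subendpoint,tumor,other,0,,0,,1,11,1,11,NA,,1,NA
category,sperm,,1,,15,,42,,34,,24,,51,36
subendpoint,sperm,morphology,1,3,3,39,10,64,9,67,10,42,14,12
subendpoint,sperm,motility,0,,8,102,21,44,21,56,6,31,25,14
subendpoint,sperm,testicular spermatid count,0,,4,40,9,84,8,111,5,58,12,11
subendpoint,sperm,epididymal sperm count,0,,4,79,12,64,7,29,10,159,15,13
subendpoint,sperm,semen sperm count,0,,5,58,11,90,12,65,4,36,15,8
category,histology,,0,,34,,95,,103,,27,,111,20
subendpoint,histology,prostate,0,,2,398,17,30,15,44,6,31,19,7
subendpoint,histology,seminal vesicle,0,,3,158,8,25,10,41,1,50,11,2
subendpoint,histology,epididymis,0,,6,153,25,20,25,23,9,17,27,7
subendpoint,histology,epididymis (spermatogenesis-specific),0,,5,62,22,67,22,68,4,50,26,8
subendpoint,histology,testis,0,,11,159,29,56,35,69,4,127,39,8
subendpoint,histology,testis (spermatogenesis-specific),0,,23,96,65,56,71,57,17,32,77,16
category,weight,,0,,42,,176,,174,,58,,196,50
subendpoint,weight,prostate,0,,3,342,40,64,29,100,16,42,42,16
subendpoint,weight,seminal vesicle,0,,4,274,36,41,29,36,14,138,39,20
subendpoint,weight,epididymis,0,,5,294,34,54,25,45,21,81,37,27
subendpoint,weight,testis,0,,36,88,153,56,154,56,47,83,172,36
total,,,2,,64,,224,,221,,84,,248,63
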