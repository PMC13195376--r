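group_type,group,age_group,mnehrc_n,census_n
sex,male,all,2482165,2835448
sex,male,0-17,557640,673827
sex,male,18-44,857548,1012726
sex,male,45-64,612529,714245
sex,male,65+,454448,434650
sex,female,all,2789026,2871046
sex,female,0-17,531812,643634
sex,female,18-44,1027682,992022
sex,female,45-64,688909,720747
sex,female,65+,540623,514643
race,aian,all,38614,57046
race,aian,0-17,9944,17486
race,aian,18-44,16504,21439
race,aian,45-64,8745,12859
race,aian,65+,3421,5262
race,asian_hpi,all,259865,300081
race,asian_hpi,0-17,74740,83539
race,asian_hpi,18-44,113407,140585
race,asian_hpi,45-64,50488,56245
race,asian_hpi,65+,21230,19712
race,black,all,460302,392850
race,black,0-17,148679,135497
race,black,18-44,200991,161303
race,black,45-64,83392,72834
race,black,65+,27240,23216
race,hispanic,all,256188,345640
race,hispanic,0-17,81608,126873
race,hispanic,18-44,116815,150957
race,hispanic,45-64,46029,54280
race,hispanic,65+,11736,13530
race,white,all,3923405,4353880
race,white,0-17,690332,844827
race,white,18-44,1311314,1438283
race,white,45-64,1048115,1197790
race,white,65+,873644,872980
race,other,all,336761,256997
race,other,0-17,85216,109239
race,other,18-44,128012,92181
race,other,45-64,65072,40984
race,other,65+,58461,14593
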