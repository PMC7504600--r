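id,category,years_formalin,age,t1_mean,t1_sd,t2_mean,t2_sd,sex,vsd,pulmonary_valve,surgery
1,D-TGA,29,18,180,53,30,6,F,Y,,VSD and atrial switch
2,D-TGA,40,12,141,37,34,6,F,,,Atrial switch
9,D-TGA,37,15,172,57,32,7,F,Y,PVS,VSD and Atrial switch
10,D-TGA,41,14,117,41,26,8,M,Y,,unoperated
11,D-TGA,43,1,165,37,33,4,M,,,Atrial switch
12,D-TGA,42,10,139,32,27,4,M,Y,PVS,Rastelli
18,bi. sys RV,47,6,132,103,30,10,M,Y,PVA,
15,bi. sys RV,45,3,180,48,34,8,F,,,
21,D-TGA,30,3,122,36,42,11,F,,,Atrial switch
22,D-TGA,37,5,161,8,35,8,M,Y,,Arterial Switch
14,L-TGA,42,21,119,14,33,4,,Y,,
3,TOF,30,34,156,21,27,7,M,Y,PVS,Repair
4,TOF,44,17,152,40,29,6,M,Y,PVS,
5,TOF,37,1,201,21,38,0,M,Y,PVS,Systemic-pulmonary shunt
6,TOF,56,,122,5,22,1,M,Y,PVS,Repair
7,TOF,57,17,141,44,24,3,M,Y,PVS,Repair
8,TOF,41,4,207,47,35,5,M,Y,PVS,Repair
19,TOF,50,,69,67,23,4,,Y,PVS,
20,TOF,35,15,97,43,32,5,M,Y,PVS,Repair
23,TOF,32,3,153,6,35,7,M,Y,PVS,Repair
24,TOF,54,4,103,53,26,10,M,Y,PVS,Repair
13,uni. sys RV,42,1,178,67,31,5,M,,PVA,Systemic-pulmonary shunt
17,uni. sys RV,31,46,183,37,38,6,F,,PVA,
16,SIT,41,1,109,118,40,8,F,,,
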