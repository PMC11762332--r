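subject_id,age,sex,status
1,78,Male,MCI
2,80,Male,Healthy
3,70,Male,Healthy
4,73,Female,Healthy
5,74,Male,MCI
6,77,Female,Healthy
7,87,Female,Healthy
8,85,Female,Healthy
9,82,Female,MCI
10,71,Female,Healthy
11,72,Female,MCI
12,65,Male,MCI
13,75,Male,Healthy
14,71,Female,MCI
15,76,Male,Healthy
16,75,Female,MCI
17,83,Male,Healthy
18,76,Male,MCI
19,80,Female,Healthy
20,79,Male,Healthy
21,75,Male,Healthy
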