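fold,role,status_in_table,subject_id
1,train,MCI,6
1,train,MCI,12
1,train,MCI,13
1,train,MCI,15
1,train,MCI,17
1,train,MCI,19
1,train,Healthy,3
1,train,Healthy,5
1,train,Healthy,8
1,train,Healthy,9
1,train,Healthy,14
1,train,Healthy,16
1,train,Healthy,18
1,train,Healthy,21
1,train,Healthy,22
1,test,MCI,1
1,test,MCI,10
1,test,Healthy,2
1,test,Healthy,7
1,test,Healthy,11
1,test,Healthy,20
2,train,MCI,1
2,train,MCI,6
2,train,MCI,10
2,train,MCI,12
2,train,MCI,15
2,train,MCI,19
2,train,Healthy,2
2,train,Healthy,5
2,train,Healthy,7
2,train,Healthy,8
2,train,Healthy,9
2,train,Healthy,11
2,train,Healthy,16
2,train,Healthy,18
2,train,Healthy,20
2,train,Healthy,21
2,test,MCI,13
2,test,MCI,17
2,test,Healthy,3
2,test,Healthy,14
2,test,Healthy,22
3,train,MCI,1
3,train,MCI,10
3,train,MCI,12
3,train,MCI,13
3,train,MCI,17
3,train,MCI,19
3,train,Healthy,2
3,train,Healthy,3
3,train,Healthy,5
3,train,Healthy,7
3,train,Healthy,9
3,train,Healthy,11
3,train,Healthy,14
3,train,Healthy,18
3,train,Healthy,20
3,train,Healthy,22
3,test,MCI,6
3,test,MCI,15
3,test,Healthy,8
3,test,Healthy,16
3,test,Healthy,21
4,train,MCI,1
4,train,MCI,6
4,train,MCI,10
4,train,MCI,13
4,train,MCI,15
4,train,MCI,17
4,train,Healthy,2
4,train,Healthy,3
4,train,Healthy,7
4,train,Healthy,8
4,train,Healthy,11
4,train,Healthy,14
4,train,Healthy,16
4,train,Healthy,20
4,train,Healthy,21
4,train,Healthy,22
4,test,MCI,12
4,test,MCI,19
4,test,Healthy,5
4,test,Healthy,9
4,test,Healthy,18
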