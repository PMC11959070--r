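age_group,gender,parameter,mean,sd
20-29,M,height,175,15
20-29,M,weight,77,10
20-29,M,heart_rate,64,11
20-29,M,distensibility,7.8,2.5
20-29,M,tpr,1.15,0.26
20-29,M,map,89,8
20-29,F,height,175,15
20-29,F,weight,61,7
20-29,F,heart_rate,69,13
20-29,F,distensibility,8.9,2.5
20-29,F,tpr,1.15,0.26
20-29,F,map,86,8
30-39,M,height,175,15
30-39,M,weight,79,10
30-39,M,heart_rate,63,9
30-39,M,distensibility,5.3,1.8
30-39,M,tpr,1.2,0.27
30-39,M,map,92,8
30-39,F,height,175,15
30-39,F,weight,66,8
30-39,F,heart_rate,59,8
30-39,F,distensibility,5.9,2.6
30-39,F,tpr,1.2,0.27
30-39,F,map,88,9
40-49,M,height,175,15
40-49,M,weight,86,9
40-49,M,heart_rate,66,11
40-49,M,distensibility,3.8,1.3
40-49,M,tpr,1.28,0.29
40-49,M,map,95,7
40-49,F,height,175,15
40-49,F,weight,65,11
40-49,F,heart_rate,67,12
40-49,F,distensibility,4,1.6
40-49,F,tpr,1.28,0.29
40-49,F,map,90,9
50-59,M,height,175,15
50-59,M,weight,77,9
50-59,M,heart_rate,63,13
50-59,M,distensibility,3.3,1.6
50-59,M,tpr,1.34,0.31
50-59,M,map,95,7
50-59,F,height,175,15
50-59,F,weight,62,6
50-59,F,heart_rate,67,9
50-59,F,distensibility,3.1,1.8
50-59,F,tpr,1.34,0.31
50-59,F,map,93,8
60-69,M,height,175,15
60-69,M,weight,79,5
60-69,M,heart_rate,65,13
60-69,M,distensibility,1.8,1.3
60-69,M,tpr,1.41,0.33
60-69,M,map,94,7
60-69,F,height,175,15
60-69,F,weight,69,15
60-69,F,heart_rate,67,8
60-69,F,distensibility,1.2,0.8
60-69,F,tpr,1.41,0.33
60-69,F,map,93,8
>70,M,height,175,15
>70,M,weight,75,9
>70,M,heart_rate,72,13
>70,M,distensibility,1.3,0.9
>70,M,tpr,1.49,0.34
>70,M,map,93,7
>70,F,height,175,15
>70,F,weight,62,9
>70,F,heart_rate,67,13
>70,F,distensibility,1.1,0.8
>70,F,tpr,1.49,0.34
>70,F,map,92,8
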