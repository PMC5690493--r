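table,metric,mean,sd,min,max
table1,local_2_2,96.7,3.7,84.4,100.0
table1,global_2_2,98.7,1.8,92.7,100.0
table1,median_dd,0.0,0.6,-0.9,1.3
table2,local_2_2,88.1,5.3,73.4,98.0
table2,global_2_2,96.3,2.6,90.4,100.0
table2,global_3_2,98.7,1.2,95.3,100.0
table2,median_dd,1.0,1.2,-1.1,2.9
table3,local_2_2,91.0,5.5,75.5,98.3
table3,global_2_2,97.1,3.6,84.1,99.8
table3,global_3_2,99.3,1.5,93.2,100.0
table3,median_dd,0.7,1.2,-1.6,3.1
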