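age_y,sex,body_weight_kg,height_cm,hematocrit,cardiac_output_L_min,blood_volume_L,gfr_L_h
1,male,10,76,0.35,1.2,0.78,1.7
5,male,19,109,0.37,3.4,1.4,3
10,male,32,138,0.39,5,2.4,4.3
15,male,56,167,0.42,6.1,4.5,5.8
18,male,70,176,0.43,6.5,5.2,6.4
30,male,73,176,0.43,6.5,5.3,6.5
50,male,73,176,0.43,6.5,5.3,6.5
70,male,73,176,0.43,6.5,5.3,6.5
100,male,73,176,0.43,6.5,5.3,6.5
1,female,10,76,0.35,1.2,0.78,1.7
5,female,19,109,0.37,3.4,1.4,3
10,female,32,138,0.39,5,2.4,4.3
15,female,53,161,0.39,5.5,3.6,5.2
18,female,59,163,0.39,5.9,3.9,5.6
30,female,60,163,0.39,5.9,3.9,5.6
50,female,60,163,0.39,5.9,3.9,5.6
70,female,60,163,0.39,5.9,3.9,5.6
100,female,60,163,0.39,5.9,3.9,5.6
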