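age_band,sex,category,n
<5,female,A,10
<5,female,B,5
5-19,male,A,2
5-19,male,B,8
20-49,female,A,6
20-49,female,B,6
50-69,male,A,12
50-69,male,B,3
70+,female,A,20
70+,female,B,10
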