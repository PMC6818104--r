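age_band,sex,year,person_years
<5,female,all,2000
5-19,male,all,4000
20-49,female,all,6000
50-69,male,all,3000
70+,female,all,1000
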