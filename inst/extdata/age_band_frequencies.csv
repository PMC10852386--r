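band,age_min,age_max,count
<1,0,0,2484
1-5,1,5,7654
6-10,6,10,4292
11-17,11,17,8663
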