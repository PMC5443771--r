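group,category,region,time_lo,time_hi,freq_lo,freq_hi,peak_time_ms,peak_freq_hz
C4C6,middle,1,0,25,125,225,13.1,153.0
C4C6,middle,2,0,25,50,125,11.7,79.5
C4C6,middle,3,25,50,0,75,36.2,13.0
C5,middle,1,10,25,75,125,21.5,100.5
C5,middle,2,30,45,25,100,35.5,83.0
C4,low,1,20,30,0,100,27.8,55.0
C6,low,1,5,25,75,125,18.7,100.5
C6,low,2,30,50,0,100,30.6,83.0
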