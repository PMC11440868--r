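activity_MBq,dose_Gy
15,2.34
20,3.70
30,5.33
40,7.71
60,10.61
80,12.51
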