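organ,tia_MBq_h_per_g,mass_g
tumor,19.8,0.126
bladder,11.86,0.10
kidney,1.37,0.30
liver,0.48,1.20
heart,2.60,0.15
brain,0.83,0.40
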