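source,target,S_Gy_per_MBq_h
tumor,tumor,0.064
bladder,bladder,0.064
kidney,kidney,0.064
liver,liver,0.064
heart,heart,0.064
brain,brain,0.064
tumor,bladder,0.0005
bladder,tumor,0.0005
kidney,liver,0.0008
liver,kidney,0.0008
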