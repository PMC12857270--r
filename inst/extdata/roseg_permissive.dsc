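# Permissive ROSE-G/ROSE-like search descriptor: terminal hairpin with the
# conserved core paired across the Shine-Dalgarno side, any base opposite
# the motif bulge, window ending in the start codon.
s1 h1 s2 h2 s3 h2' s4 h1' s5
s1 0 ***
h1 0:0 ****NT:RG****
s2 0 G
h2 0:0 NU****:****RG
s3 0 NNN****
s4 0 *
s5 0 *******NNAUG
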