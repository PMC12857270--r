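# Restrictive ROSE-G descriptor: requires the CU-G-CU core (CUGCU) and a
# bulged G on the Shine-Dalgarno side (the double bulged-G arrangement),
# excluding previously characterized ROSE-like elements.
s1 h1 s2 h2 s3 h2' s4 h1' s5
s1 0 ***
h1 0:0 ****CT:RG****
s2 0 G
h2 0:0 NU****:****RG
s3 0 NNN****
s4 0 G
s5 0 *******NNAUG
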