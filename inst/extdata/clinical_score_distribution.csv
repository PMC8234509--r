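reader,s1,s2,s3,s4,s5
algorithm,3227,17876,16264,9354,4659
clinicians,3761,16696,14723,4603,11597
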