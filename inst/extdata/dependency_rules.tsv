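antecedent	dependent	trigger	forced
CA-RDA-I3-01Archive	CA-RDA-I3-02Archive	0	0
CA-RDA-I3-01Model	CA-RDA-I3-02Model	0	0
CA-RDA-I3-01MA	CA-RDA-I3-03MA	0	0
CA-RDA-I3-01MM	CA-RDA-I3-03MM	0	0
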