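noS	E2,E3,E4,E5,E6,E7
E3a	E2,E3,E4,E4ext,E5,E6,E7
E3S	E2,E4,E5,E6,E7
E4S	E2,E3,E5,E6,E7
E5S	E2,E3,E4,E6,E7
E6S	E2,E3,E4,E5,E7
E34S	E2,E5,E6,E7
E56S	E2,E3,E4,E7
E345S	E2,E6,E7
E3456S	E2,E7
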