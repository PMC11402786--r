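>Gfp_synthetic
AAGTATCTGTCCGATGGTAGTAGAGAGTAGCTGACCGGGATCACATTTCCTACCAGCAGG
GCACGGGAGATATCATTGAATGAGCAATATACGTCTCCGATGTTTGTCGGAGCGGCCAAT
TACAACCGCGGAGTGGTAAGCTTTTATTATGAAGTAACCTAAACTATGGGAGGACCAGTC
CTTCATCTGGCAAGGAGGCAGCGCGGGAGCAGCGAAATACGCGGGAAACGTCCGTCTGCA
TCCTAGCGACATTAGAACTGGATTCTTTGCTAGGCTTGAATGAAGTCGATAGATCTCCAA
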