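>E2
GGCACAGCTTGGGAGACTTTACCAGCACTATCCATTTCGGCTTATGGTATCCCAACACTG
GCGGACGGGCAGATTAAGCCCAAACGTGCCGTCTTTATTTCTTGATGACATTGGCACCGT
TGGTGGAATCGTCCCGCTCT
>E3
GAATGATCCACGGATCAAGATCGATGACAAGCTCAACTCAGGGCCCTCGTGTTACCCTCC
CTCTGCAGTCCTCTAGTCTCCAAAGCAGCAAATGGCGCTGCGGCACTCTAGGAGGGCGAA
CCTGTACTCA
>E4
AAAGGAAAAGTGCTGATATTGTACAATGGGCACATAGTGCGCAGCAAATCTGTAAGAATG
GTCAAGCATCGACCCCTTCGAGTCTCTCACCTACCTGCCAAGTAACCCTCATAATGGCTG
>E4ext
AAACGGCAAGCTAGATTACCGCCTCATATCTCGTCCTATTGGGATCGGTCATCTTAGTCA
>E5
CCTCCCGCGCCAAATCGACTCTATTAGTCAACTCCTTTTCAACTGACATGTCGGGTGGAC
TCGGGTATTTGGTGACTCCC
>E6
TCTACAGTCAGGGTGCAGGTGCAAGGATATAGAACCTCCTCAGTTCAGACCGCATCTGCT
GACTTCGGGC
>E7
GATTCGTACGTCTCGCTTATTGCCCAACGCGCTTTGCCTAATGGAGTACTCATTCGCGTC
GTTAGTTAGC
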