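>Smu
GTTCGCCAAGGGATATACTACGAGGTGTCTTTTGCAAGATCAATTAGTAATCTGGGGTATCGTGAGTAGC
GCTGTCCTACTATGAGAGGGGGACAATTAAATGCAGGTCTCATTGGAGTACTTGATTGGTTGGACTTTCT
AAGGATGAGCATGTTGTGGGGCTACTGGAGACCTTCAAACGGCTCGAACTATGCGTGCGAGGTGGTTGGA
CGACAGACCGGGGTCTGGTCTGTATAATTTGTCGTGTGTCACTATGGTTCTGGAAGGAAGGGTGGGGGTA
GTCTGGGGGGGGCGTAGGGCAGTTTCGAGTGGCAGTGTCAAGTCCCAAGACGTAGTTGTCCGTTAGTGTA
TGATCGCGCTGGCGTCGAATTTCGGTGCGTTTACGGACGCGGCTGTAGTGAGCCCATAGCCTAAATTGAC
TTAGTTGCCCCGTTGAAGTCGGTAGTTCGGCTTGGATCAGGTGTGCAGTATCATGGCTTAAGCCTTGGCG
GCGGTTTTCGTAAATCTCATCTGAAGATGACATGTCAACCAGGGGGTGGATCAGGGCTTACTGCATGGCC
AGTACAGAGCGTGGCTATCATCAGTTGTCATGAACATTTT
>Sg1
ACGACCTTCGCTTTATGTAGCGTGGAGATCCTGCTGGGAACGCGAGGCACACTTTGGTACTAGATTCGTA
ATCTTTTGGGAAGTTTTTGCGTCTTTAGCTCCAAAGTTCAATGATTGGTAGACAGCGTTGATAGAGGCGG
TTAGGTTCGATCTGTGTGCTAGCGGGTACATCGCATGAGCCAATCGAGTGGGCTTAGTATCGCAGATCGG
TTTCTTCCGATTAACGGTGAACCATTGCCTCGGTTTGAATCAGCGGGAGGGGAGGTTAAGTCAGTGGTAC
GCCCTAAATGGGGGGGTGGGCAGGGGGGGGTAAGGTGAACGCCGCCAGTTACGGAACTCGGCGTTTAACA
GGACTGCGTGTTGAGGTCCACTTCGGGAAAGGCTGTTGCTGTAGGAAGGGTATCGGTTCACTGCTCCGGG
GAGCGATGTATTGCAGTTCGGGATGTTGTCGTTCCGATTGGCCGTCGGCTGGATCTAGTTGTAGAATGCT
TAGGAAGTAC
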