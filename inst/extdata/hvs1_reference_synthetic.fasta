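>HVS1_synthetic_reference 16024-16569 (synthetic stand-in, not rCRS)
AACAAAAACTGAAAGATACTTATGCTCTTATCTTGTTCCTAATACGGACTATGCCGAATT
CAATGGTCAAAGTGATCCCTTACACTTCCTAAACTATACACCTAGGCTCTACTCGGACAA
CATAATTTACATCAAACCAATCCTAGCTCCACATAACGCATATTCGGACATAATTTCACT
AATCTATACTCCCCTTCTCAAGAGAACGCGTTCCAACAAAATCACACTTACCCTACCGCT
ACTTCTTCTCCTATAGTAGCCTAGCGCAAATATGGCGCCACATCAGACTTCCACTAGCCA
CTTTGAGTTGTTTAAGTCTCACTAGTATTACTCCCGCGAACGCAGCACGTCTTAATACCC
TGAAAACACCACCCAAGATCCAAACACTAAAATTGATCGTAACGATAGGTTGAGGATATA
TGACATCTACGTTCCTTCACATCCAGTACTGTCCTCACCAGTAGATTTCCACCTCACTTC
GGCGCACCCGATTCTCTCCAGCTTAAAGCGCCCCACCTCCTCCATCACAACTTAAAGCTA
ATATTT
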