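gene,role,forward_primer,reverse_primer,amplicon_length_bp
CASP3,target,GGGATTGAGACGGACAGTGG,TGAACCAGGATCCGTCCTTTG,136
CLU,target,CATGAAGTTCTACGCGCGTG,AGTAGAAGGGGGAGCTCTGG,92
ERCC4,target,ATGGGAAGCACTGACCGAAG,GAACACGTCCTGTCGTCACT,114
GATA4,target,AGAAAACGGAAGCCCAAGAAC,CCACACTGCTGGAGTTGCTG,109
HK2,target,CAGCAGAACAGCCTGGATGA,GGATGGCTTCCTTCAGCAGT,106
MEF2C,target,TAACATGCCGCCATCCGCCC,ATCCTCTCGGTCGCTGCCGT,151
HIF1A,target,NA,NA,NA
GAPDH,reference,TCCACCCACGGCAAGTTCCAC,ATGTTGGCGGGATCTCGCTCCT,104
HPRT1,reference,CCCAGCGTCGTGATTAGTGA,ATCTCGAGCAAGCCGTTCAG,131
PPIA,reference,GTCTTCTTCGACATCGCCGT,TCCTTTCTCCCCAGTGCTCA,120
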