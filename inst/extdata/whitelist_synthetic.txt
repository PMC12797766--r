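AAAGTAGTCAAGCCTA
CACGGCGGATAACGTT
ATTTAGGCCGAGGTTT
CAGAAGGCATCATTGC
CCCTAAAAACTCGCAG
CCGTACCACGATCGAT
CTCGGAGCAAGTTAAT
TTCGTACAACTAAGCC
GGTATCGCTATGAAAC
AGTCAAGGATCTGGCT
ATACCCCCTTACCCAA
TTACTTAGAGACTCGA
AGGTACAAAACACGTT
AAGTCTCGCATCGGAC
CGGACCCTTCGAGCTC
TCTTCAGAACCTGCCG
CGACTGGAGATACTAC
AGTCTTCGTGCTAGCG
TACTTGCGCGGACGTT
CGGAGGTATTCAAACT
GAACCTATGGTGACAA
CAAAGGGACTAGATCA
TGCCCCTACCAGATGG
AAATCCAGCAAAGCGA
TTTAAAGTTGGGAAGT
CTCAGTTTACAATCTT
TGTTGCAGGGATAGGG
CACCCTACCATTTGGT
GTCAGCACGGGGGTCA
AAGTTTGGCCAAACAA
TGATCTTGACAGGTGC
ACCCCCAGTCCGTCAT
ACCTTGCAGAAGTACG
GACCGGATACAACAAA
ACACGATATAAATGTG
TACGCGTAAGAGATGC
CGCATCTGTAATGTGA
TTTACATACGGTTAAC
ACTGCGGCTATTATGC
CTAAGCGTGAGGATAC
CAATTGTCACCAAGCA
GTGATGCGGCTGTGCT
AATATAAGACCAATTA
GTATATACGGAATGGG
TTTTACCGCTGGTGAT
ATGCTGCAATGTATTC
CTCCCCGCCTCTGCGA
AGCTGTCTCTGGTCAT
TGCCCTCAAACAGTGC
CAAATCTTCGCCGTTA
CGCAGTTAGTAAGGAG
CTCCGCTTGTGAAGTG
TTATGAGCGGTTAGAA
CCATAAGTTCTGAAGA
TCGACTCGTGCTTGGT
GCGCAACTATATAACC
CGGACCCGCATATCAC
TCCCGCATGGCTCCGA
TAAGTTGCTGACTCGC
CTTGTGCGCCAAATCC
GCGTAAACTAATCCTG
AATAGTACCCAGTTTT
CGCGTAAGTTTCGCGG
CCCTCGGAACCGGTAT
TTAACTCATGTCGGTT
GAGTGAGACGTAAGGG
TTGTTTGTACACGCAT
CGACTGAGAGATCGGT
AGGAATAAGACCATGC
AGTCTAGTGCGGAACA
TCCTGCGGGGCCCCTA
GAGACGATTCTTCTAA
CGGATGCCAGGTCCGG
ACATCCTTAAAATAAC
TGTACTTGTTGATCTT
AACCTAGACACAGGAA
TTCTCACACTATATCG
AAAGCCATCCTTTTTC
GTTTGCATAACCTAGT
CCTTTGGATCTGAAAA
TAGTCTACGGCGCACT
ATGAACGGTGCGCCCA
TCGAGCCAATACGCAT
CTGACCGATTTTATAA
TATCCGGGACGTGGCT
TTACTGTCAATTGACA
ATGCGGGAGCTCAACG
TTGCGACAAGTACAAC
GCACGGCACAGTGTTC
TGATGCTAGCGAGGCT
TTGGTCACTGTAGGTC
GCTAAAAACCTAGTGG
CGCTGGCAACTTAACA
GCTTCACTCTGCAGCA
ATTTCTTGGCAAGTGG
TGCTTTTGGCTACATC
GATAGAAGGGGATCTT
AAACACTATGGTCATT
GGTGATGTCGGGGAAG
GCGCGGGTCGGTAAAG
AATATGGTTAGCACCG
AGGAGGCCAAAGTCTA
ATGGAGCAGGATGGTT
GCTCCTGGTTGCATGT
TGTCTACAAAGACGTA
CCGCTCTACCAACCTG
AGACTCGGGTAGGTCT
CGCAGAAGCTCTGCCA
ATCTAAACGGGCGGCG
GGCTGCGCGGCCGGAC
AGAGGATTCAGTTGCT
GAACGCGAATTGAGCC
GGCGAGCATCCCCACA
GCGTTTAAGCTTGAAT
CGCTGCGGCTTGGCCA
GCACTCTAACTCGGCG
TAGAGCCGAGCCGGAT
CCAGATAGTTTCCTTA
CGGTTGTTCTCATAAT
GCCGGCAGTGAAAATT
CTTGCCCGAGCCGCAG
GCTGCGCTAATGGTGA
ATTTCCGCTCCATACG
CATATTAGATCCCTGC
TTTTAATTTTACCACA
TACACTCCTTGCGGTC
CTCATCAGTCTGGCCT
TCACCCAAAGAACCAC
ATCCCGTAACTTTAAA
TAGGCCGTTACCAGTC
TGATCCAATGGGTCGC
TCATAGCCCGCGGATG
AACTCCCACCACAAAC
TGTTGTGGTGATAGTA
GGTACTATTTTGTCTC
GCGGTCGACGGGACAG
CAGGAATAAGCATAAG
ATCGTGACTAAGCAGT
ACCGTGCCAAATTAGA
ATGCTCCACGACCAGG
AAGCAGGGAGTTATGT
TAAGGCACATTGTAAT
TTTGTAATTACCGAAT
CGTCGAATGACTCCTT
TCACGCATAGGGCCAC
TCCCCGAGAATACTGG
TAGCGGCTAGTCTCAT
TACGTCCACATAAGCG
ACGACAGCGTCACGGG
TAGTGCGTGGGGTGGA
GTTTGTGCAACTCTAG
TTGGGCAGTTCAGGTA
CTCTGCGTAAATGATA
GGTCGCTTAGGAAGCG
CGCCTTTCCGGTGTCT
GCTACTGAGGATTGAG
ATGGGCGGCTTCGATC
AGAATCCATGGACGCG
GTTCAACGCCGCAGTT
TCCTTGCCTGAAGCAC
TGACTAACGCCCTTGT
AAAGGAGCATTGCAGC
GCTAGTACGATGAAGC
CCACTGGCACCGGCCC
TAGGGGCAGTGCTACG
CCGTAGTTGATACGAG
AGCAGACTTAAGCCCT
TAAGGACGCAGTGAAT
TCCGTATTCAATATCT
GACTCAGGAAGCGAAC
ACCTTAAAGAAGTTGG
TGCAGGTTCGAGAGTT
TAACCCAAAACGAACG
CTGGACAGCCGACAAA
CGAATATATAGAACCT
TTTGATGAACGCCTCC
AAAACCGTCAGTGTCG
GTCCACCCGTATAGCA
ATCGAGAGCGCCCCCG
CTATTTACCTAAAGAT
GTTATACATCCTGCTC
CCAATGCGTGCAGAGG
ACTCTGCGGGGTCTAC
ACTTTGATACTCTCCG
TTTTGAATAATGGGCG
TGTGTACGAACGAGTT
ACCGGTTAGTTCCGTC
ACGGGGAATAGCTTAT
GCTCTGCTATAAGGAT
GAACCTTCCGTTTGCT
TCTTTGACCCCAGCTT
CTAGAGCCGGGTCCTT
TGGGACAGGTTAGGAC
ACTGTTTGCGTTGTTC
TGCAGCTTTCTCATAC
TCGATCGCGCTTCGCT
CTGGCTTAAAAGGACG
ATCGTTCATGCAATTG
GACAACGATCGGCAGT
GGTCGGATGCCTCGTC
AAGTCGGGATCAGGAG
CCTCTGGTGTCCGCGA
TCGCGTGGTCTGCTAG
CCGAGAAAAGATACCG
ATAGAGCACACTTCCC
ATGACAACCGCTGTCA
GGGCCACACGCGTTTT
TGTGTGCTAGAGTGAA
TTAGAGTCGGAGGACG
AAGTAGCAGGCCCGTT
TTTATCCGAGAGGAAA
CCATCGGATATCGGTA
GGCTTGAACACAACGG
GCGCAGATTACTTCGT
TGCAGTTGAGCGCTTC
GTGAAAAAAAAGTCGG
TCGTTAGCATACGCAA
CGCGTGGCACCTAGCT
TTCTAATTTCGCCCTT
ATCAATACGGCGTTCT
GGCTGTTCCTGGACAA
CAGAAACGGGTCGCCC
CCTATCCCCCCTTAAT
AAAGCACTTCCGTCGA
GCGCCTTCCAAAAAGC
AACCTTCGTTTACGTT
CTTCATGGCTTCGGCA
TCGGTAGCTACTGACA
ACATGGAAGTTAGATA
CTGTGTATCCGCTGAT
GGGACTAAGCACCCAT
ACCAAGAGGTCACTCC
CCTCGATTGTTCGGCA
ACTCGCGACACTCCCT
TGGATGTGGTAAATCA
TCCGATAATAAGGGAC
ACGGACCGTAAAATCA
CTTTCTCCTAGTAAAA
TGTACCCTTCCTTCGA
ACATATGTAAAAGATA
GAGGTGTAATAAGGGG
GACCCAAGCCGAACTA
TGATGGGGAATCACTA
ACCTTCTTTGCAAGTC
CCATCAATCGCTTGTT
AACATTCTAAACGGTC
TTTTATGAGACCCGCA
GGAGACGCTATTCGCC
ATGGGATCGCCACGCA
CCTTAATCGGTCCGCG
GTTACCTATGAGGTGA
CTGGATCGGTGCTCAT
ACCTTTCCAGAACACG
TCATTGCTGTCCTGTT
GCTGACACGTTTGCCG
CCAGTTTGGCCCCATG
CTGGTCACGTTGCACC
GAAGCAGTCCATGGCT
AAAATCACTGAATCCC
CCTTTACCACGGGCTA
CAACAATGGTGATGGT
TTTACGTACCCAGGCG
TTCTCCAACGATATTA
AGGTTGCAGTGTACTA
AGTATTATTGCCAACA
GTACCTGTTTACGTTC
CTTCGCAAGGAATTCA
GTGCGGATGCCACTTA
TGACGTGTGTCAAACT
CTGGCTGTTTTACTAT
ACTATTCTTTTTGAGC
AGAAATAAGTCAGACT
CGATTCGAGCTATTGG
ACGAGGCTGTTTCGTC
CCGGCACTCTGCCGTT
GAGGCAGTTGCTAACA
CAGACTTGACCTACCG
TTTTGGATGCGCCACA
TGAGGCCACGAGACGT
CTTTCCGATCCCCATA
CCGGTAGCGATCAAGC
GCCCGAAATTTGCCTC
GAGTCCACGTGCGAGT
AGAGGTATGAGATTAG
TCACCGAGGGCCGTTA
TTACGAAGATCCAGTG
TATGAAAAAGACAATA
GCGGAGACAGAATCGC
CCGCCATAAGACAGAT
GATTTGACTAGCATCC
GGGCCCCGTATGAATC
GAGAATTTCGGTGGTC
TCCCACATCACGATTG
GCGCTCCTGCCATGGG
GCTTTAGGAGTCCATG
GCTTACGATCAAAACA
GTAGTTACACGCTAGG
GACTCATGGCCTCCGG
TGTTGCTGGCATTGAG
GACGGTCAAGTGGCAA
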