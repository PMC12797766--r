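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
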