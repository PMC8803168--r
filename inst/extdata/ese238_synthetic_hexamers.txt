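GGATGC
GGCAAA
AGAACA
AAAATA
TTAGGA
ACCAGG
TTAAAA
CAGACT
GAGTTA
GGGGGG
GTGAAA
TGTAAT
GAAGAT
TGAGTC
CACACA
GGAATT
GGGGAG
TAATGA
CGGTTT
AGGGGC
AGGGAG
TAGGGA
AAGGGA
CGGCAG
CAGCAG
AGAAGA
AAGGCT
TAGCAA
GAGGTT
ACCGGA
TGAGGA
GAGCAG
GAGTCC
GTAAGA
AATAGG
AGAAAA
ACTATG
CAGGCT
AAGGTA
GCGATC
CCGCCG
GTCGTA
AAGGTG
AACCTA
GTTACG
AGAATG
TGCCGG
CCATAG
TAGGAG
GGGAGG
AGTGAA
ATACTA
AGGGCA
TTAAGA
GCACGG
TACGCT
AATCCC
GTAAAA
AGAAAG
TAGAGG
ACAAAA
AGAGAT
AAGAAT
GGGTAA
AGGAAG
CAGCAT
TTAGTT
CGCAGT
GGTGGA
GATGGC
GAAAAA
CTAGAA
GCAATA
CGAGCG
TGGGTG
ACGTGT
TCAACG
AAGACT
AGGCAG
AAAGGG
AACGCG
AGTTCA
GGCTGT
GGGCGG
TCATCG
GACTGG
GGGTTT
CGGGAA
GAGAAA
TGTAAG
TTATAA
TGGTAA
TCAGTG
GGTATT
AGAGGA
GGAAGA
CTGGAT
CTGCGC
GGATTA
AAGGAG
AGGATA
AGATGT
GTTTAG
CAGAAT
AACTGG
GGTGGG
AACAAA
AAAGAC
AAGTAC
CGAGAG
ATGAGA
AGGAGG
GATAGG
GGAGTT
ACGAGT
AAATAA
CCAAGA
GAGCTA
AGAGAG
GCGTGG
GGAACG
GGAAAG
TGTTAG
CGGGGG
AATCGC
AAAGTC
GAGTCA
GTGTGT
AAAAAG
GCAGAG
GTGGCA
GTAGGC
TACAGG
TGAGAA
AGTAAG
GTGATG
ATATTA
CTGGCA
ATAAAT
AACGGT
AAGAAA
GGAACA
AGGGGG
TTGACC
AAATAT
AACTCC
TGAGGC
AAACCC
CAAGCC
AGACCA
TAACCA
ACCGAA
TCCGAT
TATAGA
ATGCAT
ATGGGT
AGTACA
CGCATG
GGTCGG
GCGAAT
CTCGCG
ACAGCA
TGGCAA
TGGAAA
CAGACC
ACGAAT
GCAAGG
GAGGAA
CGATAG
TTTGAG
AGAGGC
ATTCGC
AGCTAA
ATCGAA
GGGGGC
GACACT
TAATAA
AATAAT
TATTGA
TGATCA
TAGATA
GTCGGT
ACCTAA
ATGGAT
TAAACC
AGGATG
GGGGGA
AGTCGA
TTAAAG
ACTGGG
GAAGTG
ACAGAA
AACTTT
AGAAGG
GGCTTG
GATTTA
GCGACC
GCAAAT
GAGTTG
GAGGGG
CGGGGA
CAATTA
GATAGT
ATAGAG
GTTTAA
AGTGGT
GACAAA
TAATTA
GTGATA
GAGGAG
AATTTG
GTATCT
GGGGAC
GAGAGT
TGAAAA
TAAAGA
TGAAAG
AAAGGC
GGCGGA
GCGATA
AATAGC
GGGAGA
GAAGTT
GAGGGT
CCTGAC
TGTAGG
AGAAGC
AAAGAA
TTACAG
TTTGGA
GGGAAT
TGACAG
TCTGAA
AACCAG
TGGAGA
GAAGGA
AATAGA
GACCCT
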