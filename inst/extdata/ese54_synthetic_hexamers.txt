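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
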