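>allele_V_synthetic
ATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAA
TTATAATTATACCAGCAGCCTTAGATCTGGAACAAATGTGATAATTATAATTATAATTATAATTATAATT
ATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAA
TTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTAT
AATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATT
ATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAGACGTCATAATTATAATTATAATTA
TAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAAT
TATAATTATAATTATAATTATAATGGCGCCATAATTATAATTATAATTATAATTATAATTATAATTATAA
TTATAATTATAATTATAATTATAATTATAATTATAAAGTAAGAAGAGGACAGGCGGAGGAAGGAAATAAT
TATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATA
ATTAT
>allele_I_synthetic
ATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAA
TTATAATTATACCAGCAGCCTTAGATCTGGAACAAATGTGATAATTATAATTATAATTATAATTATAATT
ATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAA
TTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTAT
AATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATT
ATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAGACATCATAATTATAATTATAATTA
TAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAAT
TATAATTATAATTATAATTATAATGGCGCCATAATTATAATTATAATTATAATTATAATTATAATTATAA
TTATAATTATAATTATAATTATAATTATAATTATAAAGTAAGAAGAGGACAGGCGGAGGAAGGAAATAAT
TATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATA
ATTAT
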