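# Recombination-count spectrum of 1500 phased MHC haplotypes (750 animals)
# from the Mauritian cynomolgus macaque population: n_k haplotypes whose
# most-parsimonious founder-mosaic decomposition needs exactly k crossovers.
k	n_k
0	1030
1	382
2	74
3	14
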