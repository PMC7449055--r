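>exon8_context_K variant_at=15 genomic_start=1802251 note=reconstructed 23-nt 5' exon-8 context, K (reference, AA) allele; synthetic flanks
CCTGCCCTGCCAAGAAGGGCTGC
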