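# Synthetic exonic-splice-enhancer hexamer panel for tests and examples.
# A small purine-rich stand-in for the published 238-hexamer vertebrate
# ESE panel (not shipped here); includes AGAAGG and AAGAAG, the two motifs
# relevant to the K232A worked example. Supply your own panel file for
# real analyses (one 6-mer per line, '#' comments allowed).
AAGAAG
AGAAGG
GAAGAA
GAAGGA
TGGAAA
CAGAAG
GATGAA
AAGCAA
ACTTCA
TTCAAG
GAAGAT
CTGAAG
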