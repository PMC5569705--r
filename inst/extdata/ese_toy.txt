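# toy exonic-splice-enhancer hexamer set for tests and examples.
# purine-rich 6-mers in the style of RESCUE-ESE hits; the genuine
# RESCUE-ESE list is an external resource and can be supplied instead.
GAAGAA
AAGAAG
GAAGGA
TGGAAG
CAGAAG
GATGAA
AAGACG
GAAGAT
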