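>mirt1cN_synthetic reconstruction of a 5p-arm mirtron with the reported mirt-1cN sequence features (donor GTGAGA, G-quadruplet at position 15, PPT GTTCTTCTTT, terminal CAG); NOT the published hairpin
GTGAGACTTCATCAGGGGTTATAGTGAAGCCACAGATGTATAACCCCTGTTCTTCTTTCAG
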