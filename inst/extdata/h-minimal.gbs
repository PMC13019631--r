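! Tiny synthetic even-tempered hydrogen sets for the worked examples.
! Gaussian94 layout: orbital basis block.
H 0
S 1 1.00
   1.20 1.0
S 1 1.00
   0.30 1.0
****
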