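# synthetic generating truth for the simulate command (demonstration)
curves:
  SMX:
    top: 100
    ec50: 0.612
    hillslope: 2
  SMZ:
    top: 100
    ec50: 3.235
    hillslope: 1.5
mixture_model: CA
components: [SMX, SMZ]
additive_sd: 3
replicates: 3
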