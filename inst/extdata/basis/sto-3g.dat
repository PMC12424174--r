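! STO-3G minimal basis (Hehre, Stewart, Pople least-squares fits).
! Used for fast internal validation runs only.
****
H 0
S 3 1.00
      3.42525091             0.15432897
      0.62391373             0.53532814
      0.16885540             0.44463454
****
He 0
S 3 1.00
      6.36242139             0.15432897
      1.15892300             0.53532814
      0.31364979             0.44463454
****
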