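rules:
  - field: Ncal
    kind: numeric
    min: 2.0
    max: 3.0
  - field: leuco
    kind: numeric
    min: 3.0
    max: 10.0
  - field: hb
    kind: numeric
    min: 115
    max: 170
  - field: mono
    kind: numeric
    min: 0.2
    max: 1.0
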