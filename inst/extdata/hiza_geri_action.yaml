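rules:
  - name: hiza_geri_kf1
    expr: ((A1 > 120) and (A2 > 120))
  - name: hiza_geri_kf2
    expr: (((A1 > 50) and (A1 < 110)) and (A2 > 135))
  - name: hiza_geri_kf3
    expr: ((A1 < 40) and (A2 < 110))
actions:
  - class: hiza_geri
    sequence:
      - hiza_geri_kf1
      - hiza_geri_kf2
      - hiza_geri_kf3
    max_gap: 1.0
    max_span: 2.5
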