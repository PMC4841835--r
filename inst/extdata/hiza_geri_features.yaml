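topology: K2
features:
  - name: A1
    kind: numeric
    expr: angle(sub(joint(KneeRight), joint(HipRight)), sub(joint(SpineShoulder),
      joint(SpineBase)))
  - name: A2
    kind: numeric
    expr: angle(sub(joint(AnkleRight), joint(KneeRight)), sub(joint(SpineShoulder),
      joint(SpineBase)))
  - name: A3
    kind: numeric
    expr: angle(sub(joint(KneeLeft), joint(HipLeft)), sub(joint(SpineShoulder), joint(SpineBase)))
  - name: A4
    kind: numeric
    expr: angle(sub(joint(KneeRight), joint(HipRight)), vec(0, 1, 0))
  - name: A5
    kind: numeric
    expr: angle(sub(joint(AnkleRight), joint(KneeRight)), vec(0, 1, 0))
  - name: A6
    kind: numeric
    expr: angle(sub(joint(KneeLeft), joint(HipLeft)), vec(0, 1, 0))
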