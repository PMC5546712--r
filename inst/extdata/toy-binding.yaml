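name: reversible-binding
schema: dendsig-model-v1
species:
- name: A
  loc: cyt
  D: 0.0
  init: 100.0
- name: B
  loc: cyt
  D: 0.0
  init: 60.0
- name: C
  loc: cyt
  D: 0.0
  init: 0.0
reactions:
- eq: A + B <-> C
  kf: 0.01
  kr: 1.0
  units: /nM/s
  tag: binding
moieties:
  A:
    A: 1.0
    C: 1.0
  B:
    B: 1.0
    C: 1.0
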