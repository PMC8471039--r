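name: fig4c
params:
  v: 1.0
  k: 1.0
  omega: 4.0
  u_max: 5.0
  u_min: -5.0
  a: 0.29999999999999999
  B2: 0.0
  include_wall_interaction: no
state0:
  x: 0.0
  z: 2.0
  theta: -1.57079632679489656
problem:
  id: 2.0
  theta1: 1.57079632679489656
notes: reorientation preset at height 2/k
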