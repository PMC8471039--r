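name: fig3b_w8
params:
  v: 1.0
  k: 1.0
  omega: 8.0
  u_max: 5.0
  u_min: -5.0
  a: 0.29999999999999999
  B2: 0.0
  include_wall_interaction: no
state0:
  x: 0.0
  z: 3.67052125301087129
  theta: -1.57079632679489656
problem:
  id: 1.0
  x1: 6.28318530717958623
notes: 'parallel transport preset: |V0| = 0.34 realised at z0 = 3.67052125301 with
  u_max = 5'
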