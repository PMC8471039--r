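name: fig5a
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
  z: 3.0
  theta: -1.57079632679489656
horizon: 5.0
policy:
  kind: open_loop
  u_max: 5.0
  T_switch: 1.19501169055645162
  phase: 0.0
notes: driving-policy preset
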