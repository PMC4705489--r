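format_version: 1
basins:
- label: I
  center_xi: 4.5
  center_theta: 150.0
  width_xi: 0.5873224
  width_theta: 35.0
  depth: -5.5499361
- label: II
  center_xi: 6.5
  center_theta: 150.0
  width_xi: 0.8662979
  width_theta: 35.0
  depth: -6.14102
- label: III
  center_xi: 4.5
  center_theta: 30.0
  width_xi: 0.5873224
  width_theta: 35.0
  depth: -5.6030833
- label: IV
  center_xi: 6.5
  center_theta: 30.0
  width_xi: 0.8662979
  width_theta: 35.0
  depth: -5.9986263
wall_x: 3.2
wall_scale: 0.3
wall_eps: 1.0
attr_depth: 0.1002708
attr_on: 7.0
attr_off: 20.0
switch_on: 18.5
switch_off: 20.0
plateau: 0.0
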