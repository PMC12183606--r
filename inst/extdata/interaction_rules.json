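{
  "hbond_angle": 140,
  "halogen_angle": 140,
  "hydrophobic_dist": 4.0,
  "metal_dist": 3.5,
  "salt_bridge_dist": 5.5,
  "cation_pi_dist": 6.0,
  "pi_pi_dist": 7.2,
  "pi_pi_angle": 30,
  "t_stack_dist": 5.0,
  "t_stack_angle_min": 60,
  "t_stack_angle_max": 120
}
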