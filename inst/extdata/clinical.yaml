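# Clinical liver case: 42 W delivered (120 W generator, ~65% cable loss),
# perfused liver at 37 degC with an 11 x 8.7 mm tumor near the radiating gap,
# 20 degC coolant.
case: clinical
P_in: 42.0
duration: 600
needle:
  coolant_temperature: 20
  coolant_heat_transfer_coefficient: 500
domain:
  domain_radius: 0.050
  domain_height: 0.125
  tip_clearance: 0.040
  tumor_half_length: 0.0055
  tumor_half_width: 0.00435
  tumor_center_z: 0.025
thermal:
  time_step: 0.5
  snapshot_interval: 1
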