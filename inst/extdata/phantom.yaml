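# Liver-phantom ablation: 35 W delivered at the needle for 10 min,
# tissue-mimicking medium without perfusion or metabolism, 7 degC coolant.
case: phantom
P_in: 35.0
duration: 600
needle:
  coolant_temperature: 7
  coolant_heat_transfer_coefficient: 500
domain:
  domain_radius: 0.05145     # 102.9 mm inner diameter tube
  domain_height: 0.125
  tip_clearance: 0.040
thermal:
  time_step: 0.5
  snapshot_interval: 1
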