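name: sim5_textvariant
cues:
- red
- black
actions:
- lever_press
- chain_pull
- no_action
outcomes:
- high_tone
- low_tone
shock_value: -1.0
delay_levels:
- 3.0
- 30.0
p_shock:
- cue: red
  action: lever_press
  p_shock: 0.0
- cue: black
  action: lever_press
  p_shock: 1.0
- cue: red
  action: chain_pull
  p_shock: 1.0
- cue: black
  action: chain_pull
  p_shock: 0.4
- cue: red
  action: no_action
  p_shock: 1.0
- cue: black
  action: no_action
  p_shock: 1.0
blocks:
- rule: random
  n_trials: 2000
  novel_context: no
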