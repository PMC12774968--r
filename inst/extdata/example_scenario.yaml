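# Two-location exclusion scenario at reduced scale; fields mirror sim_config()
design:
  start_dates: ['2006-01-01', '2006-03-01', '2006-05-01', '2006-07-01']
  occasions: 4
  treatment_start: 2
locations: [Barwik, Gugny]
n0: {treatment: 90, control: 80}
recruits: 15
s_monthly: 0.7
s_treatment: 1.0
p_capture: 0.45
gamma: 0.1
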