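condition_id: fixture_high_n
physics:
  mode: active
  delta_psi_mV: -150.0
  temperature_K: 310.0
  ph_ext: 7.0
  ph_int: 7.6
nhx_ext: 0.1
pka: 9.25
initial_state:
  nhx: 0.001
  gln: 0.1
  glu: 1.0
tau0: 60.0
glnk_present: yes
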