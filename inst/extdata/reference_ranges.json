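{
  "number": [0, 320],
  "growth_speed": [0.0064, 0.64],
  "shrinking_speed": [0.01, 1.0],
  "catastrophe_frequency": [0.0132, 1.32],
  "rescue_frequency": [0.005, 0.5],
  "growth_factor": [1, 50],
  "shrink_factor": [1, 50],
  "catastrophe_factor": [1, 50],
  "rescue_factor": [1, 50]
}
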