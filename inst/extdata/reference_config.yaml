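geometry:
  envelope_diameter: 2.75
  spb_diameter: 0.18
  spb_diffusion_coefficient: 0.0015
  spb_rotational_diffusion: 0.185
  mt_diameter: 0.025
  sites_per_spb: 14.0
  tether_spring_constant: 100.0
  tether_rest_length: 0.0
  initial_mt_length: 0.1
  min_mt_length: 0.000615384615385
  viscosity: 1.0
  nucleation_stiffness: 0.1
  nucleation_cone: 0.8
dynamic_instability:
  growth_speed: 0.064
  shrinking_speed: 0.1
  catastrophe_frequency: 0.132
  rescue_frequency: 0.05
  force_catastrophe: yes
  force_catastrophe_cap: 20.0
stabilization:
  growth_factor: 1.5
  shrink_factor: 8.0
  catastrophe_factor: 8.0
  rescue_factor: 15.0
  stabilization_length: 0.1
crosslinkers:
  number: 160.0
  spring_constant: 207.0
  rest_length: 0.053
  one_head_on_rate: 800.0
  one_head_off_rate: 1.0
  two_head_on_rate_scale: 3000.0
  two_head_off_rate: 0.08
  bound_diffusion_coefficient: 0.1
  free_diffusion_coefficient: 1.0
  antiparallel_only: yes
  antiparallel_threshold: -0.5
  characteristic_binding_energy: 6.0
  bell_parameter: 0.001
  capture_radius: 0.053
  quadrature_bin: 0.01
  energy_cutoff_kt: 20.0
  end_release: no
  minus_exclusion: 0.0
wall_force:
  asymptotic_force: 7.6
  tube_radius: 0.05
  euler_gamma: 0.5772156649
  const_a: 0.5416
  const_c: 4.038
  blend_length: 1.0
ratchet:
  protofilament_count: 13.0
  subunit_increment: 0.000615384615385
  stall_scale: 5.0
  thermal_energy: 4.11
control:
  timestep: 5.0e-05
  total_time: 600.0
  frame_interval: 1.0
  initial_pole_angle: 0.0
  rng_seed: 1.0
  stabilization_enabled: yes
  record_mt_detail: no
  xl_free_interval: 10.0
  xl_pair_interval: 5.0
  neighbor_interval: 20.0
  max_step_translation: 0.005
  max_step_rotation: 0.05
  steric_strength: 1.0
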