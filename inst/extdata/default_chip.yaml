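chip:
  channels:
    count: 7
    width_um: 500.0
    depth_um: 87.0
    length_um: 20000.0
    pitch_um: 1500.0
  wells:
    per_column: 6
    diameter_um: 400.0
    depth_um: 300.0
    first_y_um: 8000.0
    pitch_um: 800.0
  gap_depth_um: 92.6
  feed:
    width_um: 3000.0
    depth_um: 1000.0
    length_um: 2000.0
  mirror_symmetric: yes
fluid:
  viscosity_pa_s: 0.00089
  density_kg_m3: 1000.0
  gravity_m_s2: 9.81
measurement:
  tilt_deg: 45.0
  separation_mm: 30.0
transport:
  diffusivity_tmz_m2_s: 5.0e-10
  diffusivity_bay_m2_s: 5.0e-10
  inlet_tmz_uM: 600.0
  inlet_bay_uM: 10.0
  dosing_flow_mL_min: 0.0002198
  cell_size_um: 50.0
experiment:
  cell_line: SYN
  control_viability: 0.92
  noise_sd: 0.1
  replicates: 5.0
  days:
  - 4
  - 7
  day_scale:
  - 0.5
  - 1.0
  kappa: 0.0
  hill_tmz:
    emax: 0.4
    ec50_uM: 250.0
    hill_n: 1.5
  hill_bay:
    emax: 0.28
    ec50_uM: 0.1
    hill_n: 0.8
seed: 1
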