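exposure_s,uv_dose_mJ_cm2,perfusion_mL_min,perfusion_sd,cell_loss_pct,cell_loss_sd,est_gap_depth_um
24,480,3.95,0.57,0.8,0.2,162.1
26,520,1.56,0.32,1.8,0.6,106.6
28,560,1.18,0.27,13.2,5.6,92.6
30,600,0.58,0.12,44.2,14.0,57.3
32,640,0.12,0.01,82.8,5.1,NA
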