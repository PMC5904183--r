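# End-to-end run at the study's analysis parameters: expression floor 5,
# per-probe |log2FC| threshold 0.5, >= 3 regulated probes per gene, and the
# 6/6 control + 2/2 knockdown replicate design; Hertz fits with a 25 deg
# pyramidal tip and nu = 0.5 at the two measured tissue moduli.
seed: 1
stages:
  - name: simulate_array
    params:
      design: stiffness_4arm
      n_genes: 300
      n_reps_ctrl: 6
      n_reps_kd: 2
      effect_log2fc: 1.0
      noise_sd: 0.1
  - name: call_genes
    params:
      cond_a: ctrl-stiff
      cond_b: ctrl-soft
      floor: 5
      threshold: 0.5
      min_probes: 3
  - name: dependence
    params:
      cond_a: ctrl-soft
      cond_b: kd-soft
      floor: 5
      threshold: 0.5
  - name: afm_regions
    params:
      fit_params:
        poisson_ratio: 0.5
        edge_angle_deg: 25
        cantilever_tilt_deg: 10
      regions:
        CV:
          true_modulus_kPa: 3.6
          contact_z_um: 2
          noise_sd_nN: 0.25
          setpoint_nN: 5
          n_curves: 10
        outside:
          true_modulus_kPa: 0.27
          contact_z_um: 2
          noise_sd_nN: 0.25
          setpoint_nN: 5
          n_curves: 10
      fold: [CV, outside]
  - name: image_quant
    params:
      n_cells: 4
      cell_intensity: 50
      nuclear_intensity: 100
      background_intensity: 10
      noise_sd: 2
      measures: [ctcf, circularity, nuccyt]
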