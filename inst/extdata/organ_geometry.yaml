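# Synthetic-cohort calibration (frozen defaults).
#
# Body mixture profiles were solved in closed form against the published
# cohort anchors (body mean dose 4.2 / 4.3 / 1.8 GyRBE and body V20 ratios
# VMAT:3D = 0.36, PBS:3D = 0.33) at the cohort-average prescription of
# 33 GyRBE, then frozen. Organ dose targets are the published cohort mean
# doses per modality; organ volumes are fixed realistic choices (synthetic,
# no anatomical claim). `phi` is the fraction of an organ's target mean
# supplied by the near-prescription component, `bath_cap` caps the low-dose
# bath volume fraction, `bath_scale` (GyRBE) is the exponential falloff of
# the bath.
modality_profiles:
  "3D":  {phi: 0.70, bath_cap: 0.25, bath_scale: 3.0}
  "VMAT": {phi: 0.40, bath_cap: 0.60, bath_scale: 5.0}
  "PBS": {phi: 0.60, bath_cap: 0.25, bath_scale: 2.0}
body:
  volume_cc: 28000
  profiles:
    "3D":  {f_rx: 0.1040, f_bath: 0.250, bath_scale: 3.0}
    "VMAT": {f_rx: 0.0248, f_bath: 0.696, bath_scale: 5.0}
    "PBS": {f_rx: 0.0341, f_bath: 0.222, bath_scale: 3.0}
organs:
  bladder:          {volume_cc: 220,  target_mean: {"3D": 8.3,  "VMAT": 9.6,  "PBS": 3.8}}
  large_bowel:      {volume_cc: 800,  target_mean: {"3D": 7.5,  "VMAT": 9.9,  "PBS": 2.3}}
  small_bowel:      {volume_cc: 900,  target_mean: {"3D": 12.0, "VMAT": 13.4, "PBS": 4.1}}
  spinal_cord:      {volume_cc: 40,   target_mean: {"3D": 20.7, "VMAT": 10.8, "PBS": 13.9}}
  kidneys:          {volume_cc: 300,  target_mean: {"3D": 6.0,  "VMAT": 4.2,  "PBS": 2.9}}
  liver:            {volume_cc: 1500, target_mean: {"3D": 3.5,  "VMAT": 4.8,  "PBS": 0.48}}
  pancreas:         {volume_cc: 70,   target_mean: {"3D": 15.4, "VMAT": 15.1, "PBS": 6.5}}
  rectum:           {volume_cc: 60,   target_mean: {"3D": 5.4,  "VMAT": 7.8,  "PBS": 3.3}}
  stomach:          {volume_cc: 250,  target_mean: {"3D": 10.2, "VMAT": 7.0,  "PBS": 0.60}}
  femurs:           {volume_cc: 700,  target_mean: {"3D": 1.6,  "VMAT": 1.9,  "PBS": 0.49}}
  pelvic_ilium:     {volume_cc: 600,  target_mean: {"3D": 5.7,  "VMAT": 7.3,  "PBS": 2.9}}
  sacrum:           {volume_cc: 200,  target_mean: {"3D": 14.9, "VMAT": 12.2, "PBS": 10.1}}
  vertebral_bodies: {volume_cc: 250,  target_mean: {"3D": 21.5, "VMAT": 16.2, "PBS": 15.9}}
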