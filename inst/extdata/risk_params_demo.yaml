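# DEMONSTRATION organ risk-parameter registry.
#
# These are NOT literature estimates: every organ uses the full mechanistic
# carcinoma model with alpha = 0.1/Gy, R = 0.5, an initial EAR slope of 1
# excess case per 10,000 person-years per Gy, and no age modification.
# This set exercises all code paths and preserves between-modality orderings;
# absolute EAR/LAR values computed from it are illustrative only. Replace via
# default_risk_params(path = ...) with a transcribed literature registry for
# absolute risk estimates. Kidneys and pancreas are cloned from small_bowel
# at load time.
bladder: &demo
  model: mechanistic
  alpha: 0.1
  R: 0.5
  beta_ear: 1.0
  gamma_e: 0.0
  gamma_a: 0.0
  alpha_beta: 3
  source: demonstration
large_bowel: *demo
small_bowel: *demo
spinal_cord: *demo
liver: *demo
rectum: *demo
stomach: *demo
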