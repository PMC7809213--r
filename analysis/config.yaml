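# Scaled-down synthetic study configuration used by the numbered analysis
# scripts. Six climate bands give C(6,4) + C(6,5) = 21 candidate variable
# subsets; two pseudo-GCMs, four RCPs and both horizons exercise the full
# projection ensemble at desk scale.
master_seed: 20260922
rows: 60
cols: 60
band_names: [bio4, bio10, bio11, bio12, bio15, bio16]
correlation_length: 4
driver_bands: [bio10, bio12]
n_native: 120
n_holdout: 10
gcms: [BC, CC]
rcps: [2.6, 4.5, 6.0, 8.5]
years: [2050, 2070]
background_n: 2000
replicates: 3
gates:
  auc_screen: 0.8
  tss_screen: 0.6
  min_passing: 2
  auc_final: 0.7
  high_agreement: 0.95
screen_classes: [linear, quadratic, hinge]
knots: 15
multipliers: [1, 2]
tune_class_sets: [L, LQ, LQH]
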