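# Demo pipeline configuration: a small synthetic city that runs end to end
# in under a minute. Omitted keys take the documented defaults
# (500 trees, 10 folds, radii 50/100/200/500, 50 m cells, 30-day
# fixed-site subsample, equal index weights).
seed: 5
out_dir: soundlur_demo
city:
  extent_m: [1500, 1500]
  n_fixed_sites: 2
  n_rotating_sites: 24
  campaign_days_fixed: 12
lur:
  n_trees: 60
  cv_folds: 5
  n_perm: 3
run_cv: true
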