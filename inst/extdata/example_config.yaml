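# Example run configuration for holdoutcca::run_pipeline().
# Either a `paths:` block (CSV inputs) or a `simulate:` block
# (synth_config() arguments) must be present; unknown keys are rejected.

simulate:
  n_subjects: 800
  n_risk_factors: 20
  n_parcels: 40

scaling: raw            # raw | proportional | corrected
sample_mode: mixed      # mixed | women | men (stratified modes drop sex
                        # from the confound set and filter rows)
confound_columns: [age, sex, site]

grid: [0.0, 0.1, 0.3, 0.5, 0.7, 0.9, 0.99, 0.9999]
n_outer: 5
n_inner: 5
holdout_frac: 0.2
test_frac: 0.2

n_perm: 1000            # permutations per outer split
n_perm_spin: 10000      # spin-test rotations
alpha: 0.05
max_dimensions: 3

marker_column: marker   # column of the confounds table to associate
marker_comparisons: 1   # Bonferroni family size for that battery

seed: 1
# out_dir: results/run1 # uncomment to write CSV/JSON outputs
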