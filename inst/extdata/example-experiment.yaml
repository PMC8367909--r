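# Mid-scale linking study: baseline ability shift, 80% missing data.
J: 100
I: 10
R: 10
K: 5
seed: 1
replications: 30
new:
  scenario: 1
grid:
  C_R: [1, 2, 3, 4, 5]
  C_I: [1, 2, 3, 4, 5]
design:
  type: rater_set
  N_R: 2
drift:
  enabled: false
error:
  index: rmse
  scope: all_free
mcmc:
  iterations: 5000
  burn_in: 2000
  thinning: 2
  chains: 1
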