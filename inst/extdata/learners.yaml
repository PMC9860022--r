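# Random-search hyperparameter ranges per base-learner family.
# Ranges follow commonly published defaults for each algorithm; they are
# shipped as data so they can be versioned and overridden without code
# changes. `log10` ranges are sampled uniformly on the log scale.
boost_tree:
  n_trees: {type: int, min: 10, max: 60}
  maxdepth: {type: int, min: 1, max: 3}
svm_rbf:
  cost: {type: log10, min: -1, max: 2}
  gamma: {type: log10, min: -3, max: 0}
rf:
  num_trees: {type: int, min: 100, max: 300}
  mtry_frac: {type: real, min: 0.1, max: 0.9}
  min_node: {type: int, min: 1, max: 10}
pca_nnet:
  ncomp_frac: {type: real, min: 0.2, max: 1.0}
  size: {type: int, min: 1, max: 7}
  decay: {type: log10, min: -4, max: 0}
gp_rbf:
  sigma: {type: log10, min: -3, max: 0}
glmnet:
  alpha: {type: real, min: 0, max: 1}
  lambda: {type: log10, min: -4, max: 0}
bag_boost:
  n_bags: {type: int, min: 3, max: 6}
  n_trees: {type: int, min: 5, max: 20}
  maxdepth: {type: int, min: 1, max: 3}
xgb:
  eta: {type: real, min: 0.01, max: 0.3}
  max_depth: {type: int, min: 1, max: 6}
  nrounds: {type: int, min: 20, max: 150}
  subsample: {type: real, min: 0.5, max: 1.0}
step_glm: {}
nbayes: {}
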