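# Pinned default hyperparameters of the binary mechanism classifier bank.
# GBDT is the classical gradient-boosting configuration (shallow trees,
# small learning rate, no regularization penalty); XGB uses the library's
# regularized defaults.
RF:
  ntree: 500
GBDT:
  nrounds: 100
  max_depth: 3
  eta: 0.1
  lambda: 0
  alpha: 0
  subsample: 1.0
XGB:
  nrounds: 100
  max_depth: 6
  eta: 0.3
  lambda: 1
SVM:
  kernel: radial
  cost: 1
  gamma: scale
LR: {}
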