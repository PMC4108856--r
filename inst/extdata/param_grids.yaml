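# Parameter grid domains for the six wrapped classifiers.
LDA: {}
SVM:
  kernel: [linear, polynomial, radial, sigmoid]
  C: [1, 3, 5, 7, 9, 10, 12, 15]
  degree: [1, 2, 3, 4, 5]
  gamma: [0.001, 0.005, 0.1, 0.15, 0.2, 0.4, 0.6, 0.8, 1, 2, 3, 5]
  coef0: [0, 1, 2]
NB:
  kernel_density: [0, 1]
  discretize: [0, 1]
CMANTEC:
  Imax: [1000, 10000, 100000]
  gfac: [0.01, 0.05, 0.1, 0.2, 0.25, 0.3]
  phi: [1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5, 5.5, 6]
KNN:
  k: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
  distance: [euclidean, chi-squared, cosine-similarity]
MLP:
  n_hidden: [2, 3, 4, 5, 6]
  alpha: [0.05, 0.1, 0.2, 0.3, 0.5]
  n_cycles: [10, 25, 50]
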