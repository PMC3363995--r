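# Shared fixtures: small fixed benchmark systems built in code.

# a fixed, well-conditioned unidirectional AR pair (X -> Y, delay 1, order 2)
fixed_pair_spec <- function(gamma = 0.6)
  linear_ar_spec(alpha = c(0.5, -0.2), beta = c(0.4, 0.1), gamma = gamma,
                 sigma_x = 1, sigma_y = 1, p1 = 1, p2 = 2)

# strongly coupled single-lag pair for oracle tests
strong_pair_spec <- function()
  linear_ar_spec(alpha = 0.5, beta = 0.3, gamma = 0.9, sigma_x = 1,
                 sigma_y = 0.5, p1 = 1, p2 = 1)

gauss_cfg <- function(p = 2) di_config(p, estimator = estimator_config("gaussian"))

# analytic MI of a bivariate Gaussian with correlation r, bits
gauss_mi_bits <- function(r) -0.5 * log2(1 - r^2)
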