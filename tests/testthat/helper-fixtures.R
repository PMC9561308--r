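# shared fixtures: the four base-case survival laws and small helpers

table1_models <- function() {
  list(
    lp_os     = parametric_survival("loglogistic", 1.5396, 0.01375),
    lp_pfs    = parametric_survival("loglogistic", 1.6294, 0.04528),
    chemo_os  = parametric_survival("loglogistic", 1.8582, 0.01024),
    chemo_pfs = parametric_survival("loglogistic", 1.941,  0.06522)
  )
}

# independent median oracle: root of S(t) = 1/2, no closed form used
median_by_root <- function(model) {
  stats::uniroot(function(t) survival_prob(model, t) - 0.5,
                 lower = 1e-9, upper = 1e6, tol = 1e-10)$root
}

# one representative model per family, on a months-like scale
family_zoo <- function() {
  list(
    loglogistic = parametric_survival("loglogistic", 1.5396, 0.01375),
    weibull     = parametric_survival("weibull", 1.3, 14),
    lognormal   = parametric_survival("lognormal", 0.8, 12),
    gompertz    = parametric_survival("gompertz", 0.12, 0.03),
    exponential = parametric_survival("exponential", 1, 0.08),
    gamma       = parametric_survival("gamma", 1.5, 0.12)
  )
}
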