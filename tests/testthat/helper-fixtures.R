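# Shared fixtures: random family specs and censored datasets used by the
# property-style suites, plus a reduced MCMC protocol for unit tests.

test_config <- function(seed = 1, n_chains = 2, n_burnin = 800,
                        n_saved = 800, thin = 1) {
  mcmc_config(n_chains = n_chains, n_burnin = n_burnin, n_saved = n_saved,
              thin = thin, seed = seed)
}

ALL_FAMILIES <- c("exponential", "weibull", "normal", "lognormal",
                  "loglogistic", "binomial", "betabinomial")

random_family_spec <- function(family) {
  switch(family,
    exponential  = family_spec("exponential", rate = runif(1, 0.2, 3)),
    weibull      = family_spec("weibull", shape = runif(1, 0.5, 3),
                               scale = runif(1, 0.5, 4)),
    normal       = family_spec("normal", mean = runif(1, -2, 2),
                               sd = runif(1, 0.3, 3)),
    lognormal    = family_spec("lognormal", meanlog = runif(1, -1, 1),
                               sdlog = runif(1, 0.3, 1.5)),
    loglogistic  = family_spec("loglogistic", shape = runif(1, 0.8, 4),
                               scale = runif(1, 0.5, 4)),
    binomial     = family_spec("binomial", size = sample(5:30, 1),
                               prob = runif(1, 0.15, 0.85)),
    betabinomial = family_spec("betabinomial", size = sample(5:30, 1),
                               shape1 = runif(1, 0.5, 5),
                               shape2 = runif(1, 0.5, 5))
  )
}

# quantile of a family by inversion on a simulated grid (oracle-free helper
# for placing cutoffs in the central probability range)
family_quantile <- function(spec, q) {
  draws <- family_rng(spec, 2000)
  as.numeric(stats::quantile(draws, q, type = 1))
}

# A random dataset with a mix of all four censoring statuses whose cutoffs
# sit in the family's central probability range, so no likelihood term is
# close to the clipping floor.
random_censored_dataset <- function(family = sample(ALL_FAMILIES, 1),
                                    n = sample(2:8, 1)) {
  spec <- random_family_spec(family)
  count <- spec$support == "integer-count"
  positive <- spec$support == "continuous-positive"
  size <- if (count) spec$params$size else Inf
  # positivity floor applies only to positive-support families; forcing it on
  # the real line would push interval bounds into a far tail
  floor_cut <- function(q) if (positive) max(q, 1e-3) else q
  status <- sample(c("observed", "left", "right", "interval"), n,
                   replace = TRUE)
  value <- lower <- upper <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (status[i] == "observed") {
      value[i] <- family_rng(spec, 1)
      if (positive && value[i] <= 0) value[i] <- 0.1
    } else if (status[i] == "left") {
      q <- family_quantile(spec, runif(1, 0.2, 0.9))
      upper[i] <- if (count) max(1, min(q, size)) else floor_cut(q)
    } else if (status[i] == "right") {
      q <- family_quantile(spec, runif(1, 0.1, 0.8))
      lower[i] <- if (count) max(0, min(q, size - 1)) else floor_cut(q)
    } else {
      qs <- runif(1, 0.15, 0.55)
      ql <- family_quantile(spec, qs)
      qu <- family_quantile(spec, qs + runif(1, 0.25, 0.4))
      if (count) {
        ql <- max(0, min(ql, size - 1))
        qu <- max(ql + 1, min(qu, size))
      } else {
        ql <- floor_cut(ql)
        if (qu <= ql) qu <- ql + 0.5
      }
      lower[i] <- ql
      upper[i] <- qu
    }
  }
  list(data = censored_data(value, status, lower, upper), spec = spec,
       family = family)
}

# single-record view of a (possibly vector-parameter) family spec
spec_i <- function(spec, i, n) {
  params <- lapply(spec$params, function(v) rep_len(v, n)[i])
  do.call(family_spec, c(list(spec$family), params))
}

# tiny AE table with a mix of reported and censored studies
toy_ae_records <- function(seed = 42, n_studies = 12) {
  simulate_ae_meta(n_studies = n_studies,
                   incidence = c(Nivolumab = 0.08, Pembrolizumab = 0.1,
                                 Atezolizumab = 0.05, Avelumab = 0.06,
                                 Durvalumab = 0.07),
                   size_range = c(30, 120), cutoff = 3, seed = seed)
}
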