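# Deviance monitoring, observed-only diagnostic, DIC and PED

# small survival fixture shared across the blocks below
make_monitor_fixture <- function(seed = 33, n = 40, cens_time = 0.6) {
  dat <- simulate_censored_survival(n, beta0 = 0.2, beta1 = 0.7,
                                    censoring = list(type = "administrative",
                                                     time = cens_time),
                                    seed = seed)
  x <- dat$x
  data <- censored_data(
    value  = ifelse(dat$status == 1, dat$time, NA),
    status = ifelse(dat$status == 1, "observed", "right"),
    lower  = ifelse(dat$status == 1, NA, dat$time),
    covariates = data.frame(x = x))
  model <- function(theta) {
    family_spec("exponential",
                rate = exp(theta[["beta0"]] + theta[["beta1"]] * x))
  }
  log_lik_terms <- function(theta, idx) {
    as.numeric(censored_loglik_terms(data, model(theta), idx = idx))
  }
  samples <- run_mcmc(priors = list(beta0 = prior_normal(0, 10),
                                    beta1 = prior_normal(0, 10)),
                      config = test_config(seed = seed, n_burnin = 600,
                                           n_saved = 600),
                      log_lik_terms = log_lik_terms)
  list(data = data, model = model, samples = samples,
       dev = monitor_deviance(samples, data, model))
}

fx <- make_monitor_fixture()

test_that("per-draw deviance rows sum to -2 x the exact log-likelihood", {
  dev <- fx$dev
  expect_equal(rowSums(dev$per_obs), dev$total, tolerance = 1e-8)
  for (t in c(1, 17, nrow(dev$per_obs))) {
    theta <- as.list(fx$samples$draws[dev$chain[t],
                                      ((t - 1) %% dim(fx$samples$draws)[2]) + 1, ])
    names(theta) <- fx$samples$parameters
    e <- as.numeric(exact_log_likelihood(fx$data, fx$model(theta)))
    expect_equal(dev$total[t], -2 * e, tolerance = 1e-8)
  }
  # per-draw split identity
  expect_equal(dev$total, dev$obs_part + dev$cen_part, tolerance = 1e-10)
})

test_that("a right-censored record's deviance column is -2 log S(cut) > 0", {
  dev <- fx$dev
  cen_cols <- fx$data$C
  expect_gt(length(cen_cols), 0)
  expect_true(all(dev$per_obs[, cen_cols] > 0))
  i <- cen_cols[1]
  t <- 5
  theta <- as.list(fx$samples$draws[1, t, ])
  names(theta) <- fx$samples$parameters
  lam <- exp(theta$beta0 + theta$beta1 * fx$data$records$x[i])
  expect_equal(dev$per_obs[t, i], -2 * (-lam * fx$data$records$lower[i]),
               tolerance = 1e-8)
})

test_that("observed-only deviance reproduces the wrong-focus monitor", {
  dev <- fx$dev
  oo <- observed_only_deviance(dev)
  # difference from the full deviance is exactly the censored part, per draw
  expect_equal(dev$total - oo, dev$cen_part, tolerance = 1e-10)
  # correct-focus property: with censoring and S(cut) < 1 the full mean
  # deviance strictly exceeds the observed-only mean
  expect_gt(mean(dev$total), mean(oo))

  # with no censoring the two monitors coincide
  dat <- simulate_censored_survival(15, beta0 = 0, beta1 = 0,
                                    censoring = list(type = "administrative",
                                                     time = Inf), seed = 4)
  data0 <- censored_data(dat$time, rep("observed", nrow(dat)))
  model0 <- function(theta) family_spec("exponential",
                                        rate = exp(theta[["beta0"]]))
  s0 <- run_mcmc(priors = list(beta0 = prior_normal(0, 10)),
                 config = test_config(seed = 2, n_burnin = 200, n_saved = 100),
                 log_lik_terms = function(theta, idx)
                   as.numeric(censored_loglik_terms(data0, model0(theta),
                                                    idx = idx)))
  dev0 <- monitor_deviance(s0, data0, model0)
  expect_identical(observed_only_deviance(dev0), dev0$total)
})

test_that("monitoring through the augmented likelihood matches the exact route", {
  # equivalence lifted to the monitor: recompute per-draw totals through the
  # Bernoulli-indicator factorization and compare draw by draw
  aug <- bernoulli_augment(fx$data)
  dev <- fx$dev
  idx <- seq(1, nrow(dev$per_obs), by = 37)
  n_per <- dim(fx$samples$draws)[2]
  for (t in idx) {
    ch <- dev$chain[t]
    theta <- as.list(fx$samples$draws[ch, ((t - 1) %% n_per) + 1, ])
    names(theta) <- fx$samples$parameters
    a <- as.numeric(augmented_log_likelihood(aug, fx$model(theta)))
    expect_equal(dev$total[t], -2 * a, tolerance = 1e-8)
  }
})

test_that("DIC identities and degenerate cases hold", {
  dic <- compute_dic(fx$dev, fx$samples, fx$data, fx$model)
  expect_equal(dic$DIC, dic$Dbar + dic$pD, tolerance = 1e-8)
  expect_identical(dic$pd_estimator, "plugin")
  expect_gt(dic$pD, 0)

  # constant chains: deviance constant, pD = 0, DIC = Dbar
  const <- fx$samples
  const$draws[, , "beta0"] <- 0.1
  const$draws[, , "beta1"] <- -0.2
  devc <- monitor_deviance(const, fx$data, fx$model)
  dicc <- compute_dic(devc, const, fx$data, fx$model)
  expect_equal(dicc$pD, 0, tolerance = 1e-8)
  expect_equal(dicc$DIC, dicc$Dbar, tolerance = 1e-8)
  pedc <- compute_ped(devc, const, fx$data, fx$model)
  expect_equal(pedc$p_opt, 0, tolerance = 1e-8)
  expect_equal(pedc$PED, pedc$Dbar, tolerance = 1e-8)
})

test_that("plug-in pD matches the conjugate-shrinkage effective parameter count", {
  # normal likelihood with known variance and a conjugate normal prior:
  # the effective number of parameters equals the shrinkage factor
  # n / (n + sigma^2 / tau^2)
  set.seed(51)
  n <- 25; sigma <- 1; tau <- 0.8
  y <- rnorm(n, 0.4, sigma)
  data <- censored_data(y, rep("observed", n))
  model <- function(theta) family_spec("normal", mean = theta[["mu"]],
                                       sd = sigma)
  samples <- run_mcmc(priors = list(mu = prior_normal(0, tau)),
                      config = test_config(seed = 5, n_burnin = 1000,
                                           n_saved = 4000),
                      log_lik_terms = function(theta, idx)
                        as.numeric(censored_loglik_terms(data, model(theta),
                                                         idx = idx)))
  dev <- monitor_deviance(samples, data, model)
  dic <- compute_dic(dev, samples, data, model)
  shrink <- n / (n + sigma^2 / tau^2)
  expect_lt(abs(dic$pD - shrink) / shrink, 0.05)
  # the variance estimator agrees to within Monte-Carlo error here
  dic_v <- compute_dic(dev, samples, data, model, pd_estimator = "variance")
  expect_identical(dic_v$pd_estimator, "variance")
  expect_lt(abs(dic_v$pD - shrink) / shrink, 0.2)
})

test_that("optimism exceeds pD and the PED identity holds on both estimators", {
  dic <- compute_dic(fx$dev, fx$samples, fx$data, fx$model)
  for (est in c("asymptotic", "importance")) {
    ped <- compute_ped(fx$dev, fx$samples, fx$data, fx$model,
                       popt_estimator = est)
    expect_equal(ped$PED, ped$Dbar + ped$p_opt, tolerance = 1e-8)
    expect_gt(ped$p_opt, dic$pD)
    expect_identical(ped$popt_estimator, est)
  }
})

test_that("comparison reports flag minima and refuse mismatched datasets", {
  fit1 <- list(dic = list(Dbar = 100, pD = 2, DIC = 102,
                          pd_estimator = "plugin"),
               ped = list(p_opt = 4, PED = 104,
                          popt_estimator = "asymptotic"),
               data_fingerprint = "d1")
  fit2 <- list(dic = list(Dbar = 98, pD = 6, DIC = 104,
                          pd_estimator = "plugin"),
               ped = list(p_opt = 12, PED = 110,
                          popt_estimator = "asymptotic"),
               data_fingerprint = "d1")
  rep <- compare_models(list(simple = fit1, rich = fit2))
  expect_equal(nrow(rep), 2)
  expect_true(rep$min_DIC[rep$model == "simple"])
  expect_true(rep$min_PED[rep$model == "simple"])
  expect_false(rep$min_DIC[rep$model == "rich"])
  txt <- format_report(rep)
  expect_match(txt[1], "Dbar")
  expect_length(txt, 4)

  fit3 <- fit2
  fit3$data_fingerprint <- "other"
  expect_error(compare_models(list(a = fit1, b = fit3)), "different datasets")

  single <- compare_models(list(only = fit1))
  expect_true(single$min_DIC && single$min_PED)
})
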