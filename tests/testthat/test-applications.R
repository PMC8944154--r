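# Survival and adverse-event model presets, CSV I/O

test_that("survival CSV round-trips and rejects malformed rows", {
  dat <- simulate_censored_survival(20, beta0 = -1, beta1 = 0.5,
                                    censoring = list(type = "administrative",
                                                     time = 3), seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_survival_csv(dat, path)
  back <- read_survival_csv(path)
  expect_equal(back$time, dat$time)
  expect_equal(back$status, dat$status)
  expect_equal(back$x, dat$x)

  bad <- dat; bad$time[3] <- -1
  pb <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, pb, row.names = FALSE)
  expect_error(read_survival_csv(pb), "row 3")
  expect_error(read_survival_csv("no/such/file.csv"), "not found")

  extra <- dat; extra$age <- 50
  pe <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(extra, pe, row.names = FALSE)
  expect_warning(read_survival_csv(pe), "extra column")
})

test_that("AE CSV round-trips and enforces the censoring contract", {
  dat <- toy_ae_records(seed = 44)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ae_csv(dat, path)
  back <- read_ae_csv(path)
  expect_equal(back$n, dat$n)
  expect_equal(back$censored, dat$censored)
  expect_equal(back$count, dat$count)

  bad <- dat
  i <- which(bad$censored == 1)[1]
  bad$count[i] <- 2  # censored row with a count present
  pb <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, pb, row.names = FALSE)
  expect_error(read_ae_csv(pb), paste("row", i))
})

test_that("single observed record at fixed parameters gives the textbook term", {
  # t = 1, x = 0, beta0 = 0: lambda = 1, log-likelihood log(1) - 1 = -1
  rec <- data.frame(time = 1, status = 1, x = 0)
  d <- censored_data(1, "observed")
  sp <- family_spec("exponential", rate = exp(0))
  expect_equal(as.numeric(exact_log_likelihood(d, sp)), -1)
})

test_that("survival fit recovers generator truth on synthetic data", {
  dat <- simulate_censored_survival(500, beta0 = -3, beta1 = 0.5,
                                    censoring = list(type = "administrative",
                                                     time = 14),
                                    seed = 61)
  # administrative time chosen to censor roughly 30% of subjects
  expect_gt(attr(dat, "truth")$censoring_fraction, 0.15)
  fit <- fit_exponential_survival(dat, config = test_config(seed = 3,
                                                            n_burnin = 1200,
                                                            n_saved = 1500))
  sm <- fit$summary
  for (p in c("beta0", "beta1")) {
    row <- sm[sm$parameter == p, ]
    truth <- attr(dat, "truth")[[p]]
    expect_lt(abs(row$mean - truth), 3 * row$sd)
    expect_lt(row$rhat, 1.05)
  }
  # wrong-focus diagnostic sits strictly below the full mean deviance
  expect_lt(fit$wrong_focus_Dbar, fit$dic$Dbar)
})

test_that("posterior is symmetric across groups when the effect is absent", {
  # balanced data simulated with beta1 = 0: the two group hazards
  # exp(beta0) and exp(beta0 + beta1) have matching posterior distributions
  dat <- simulate_censored_survival(400, beta0 = -1, beta1 = 0,
                                    censoring = list(type = "administrative",
                                                     time = 6), seed = 15)
  fit <- fit_exponential_survival(dat, config = test_config(seed = 9,
                                                            n_burnin = 1000,
                                                            n_saved = 1500))
  b0 <- as.vector(fit$samples$draws[, , "beta0"])
  b1 <- as.vector(fit$samples$draws[, , "beta1"])
  h0 <- exp(b0)
  h1 <- exp(b0 + b1)
  expect_lt(abs(mean(h1) / mean(h0) - 1), 0.15)
  # the posterior for the absent effect concentrates near zero at the scale
  # of its own posterior spread (data-level sampling noise included)
  expect_lt(abs(mean(b1)), 2.5 * sd(b1))
})

test_that("model A with one uncensored study matches the conjugate posterior", {
  rec <- data.frame(study = "S1", drug = "Nivolumab", n = 40, count = 6,
                    censored = 0, cutoff = NA)
  fit <- fit_ae_model(rec, "A", config = test_config(seed = 7, n_burnin = 1500,
                                                     n_saved = 3000),
                      shape_hyper = prior_uniform(0.999, 1.001))
  # with shapes pinned to ~1 the posterior for p is Beta(1 + 6, 1 + 34)
  draws <- as.vector(fit$samples$draws[, , "p"])
  expect_lt(abs(mean(draws) - 7 / 42), 0.012)
  expect_lt(abs(sd(draws) - sqrt(7 * 35 / (42^2 * 43))), 0.012)
})

test_that("fully censored AE data pushes posterior mass below cutoff/n", {
  rec <- data.frame(study = paste0("S", 1:6),
                    drug = "Pembrolizumab", n = 50, count = NA_integer_,
                    censored = 1, cutoff = 3)
  fit <- fit_ae_model(rec, "A", config = test_config(seed = 11, n_burnin = 1000,
                                                     n_saved = 1500))
  draws <- as.vector(fit$samples$draws[, , "p"])
  # likelihood is a product of CDF terms only; mass concentrates below 3/50
  expect_gt(mean(draws < 3 / 50), 0.8)
})

test_that("AE model validation rejects unknown drugs and duplicate studies", {
  rec <- toy_ae_records(seed = 5)
  bad <- rec; bad$drug[1] <- "Unknownumab"
  expect_error(fit_ae_model(bad, "A"), "unknown drug")
  dup <- rec; dup$study[2] <- dup$study[1]
  expect_error(fit_ae_model(dup, "G"), "unique study ids")
})

test_that("DIC is insensitive to the link choice on moderate synthetic effects", {
  dat <- simulate_ae_meta(n_studies = 40, seed = 23)
  cfg <- test_config(seed = 13, n_burnin = 1200, n_saved = 1200)
  fits <- lapply(c(D = "D", E = "E", F = "F"), function(id)
    fit_ae_model(dat, id, config = cfg))
  dics <- vapply(fits, function(f) f$dic$DIC, numeric(1))
  expect_lt(max(dics) - min(dics), 2)
})

test_that("posterior coefficients agree with an independent censoring-indicator
           implementation on the aml data", {
  skip_if_not_installed("rjags")
  rec <- aml_survival_data()
  # censoring-indicator route in JAGS (the posterior it samples is correct;
  # only its deviance monitor has the wrong focus)
  jm_code <- "model {
    for (i in 1:N) {
      cens[i] ~ dinterval(t[i], t_cen[i])
      t[i] ~ dexp(lambda[i])
      log(lambda[i]) <- beta0 + beta1 * x[i]
    }
    beta0 ~ dnorm(0, 1e-4)
    beta1 ~ dnorm(0, 1e-4)
  }"
  t_obs <- ifelse(rec$status == 1, rec$time, NA)
  jd <- list(N = nrow(rec), x = rec$x, t = t_obs,
             t_cen = ifelse(rec$status == 1, rec$time + 1, rec$time),
             cens = 1 - rec$status)
  ji <- list(t = ifelse(rec$status == 1, NA, rec$time + 1),
             beta0 = -3, beta1 = 0, .RNG.name = "base::Wichmann-Hill",
             .RNG.seed = 7)
  jm <- rjags::jags.model(textConnection(jm_code), data = jd, inits = ji,
                          n.chains = 1, quiet = TRUE)
  update(jm, 4000)
  js <- rjags::coda.samples(jm, c("beta0", "beta1"), n.iter = 12000, thin = 2)
  jsum <- summary(js)$statistics

  fit <- fit_exponential_survival(rec, config = test_config(seed = 29,
                                                            n_burnin = 2000,
                                                            n_saved = 4000))
  sm <- fit$summary
  for (p in c("beta0", "beta1")) {
    ours <- sm[sm$parameter == p, ]
    theirs <- jsum[p, ]
    expect_lt(abs(ours$mean - theirs["Mean"]),
              0.1 * max(ours$sd, theirs["SD"]) * 3)
  }
})
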