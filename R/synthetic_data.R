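#' Simulate right-censored exponential survival data
#'
#' Event times are exponential with hazard
#' \eqn{\lambda_i = \exp(\beta_0 + \beta_1 x_i)} for a binary covariate
#' assigned to a fixed fraction of subjects. Censoring is either
#' administrative (everyone still at risk at a fixed time is censored there)
#' or random exponential (an independent exponential censoring time per
#' subject, the smaller of event and censoring time is recorded).
#'
#' @param n Number of subjects.
#' @param beta0,beta1 Log baseline hazard and log hazard ratio.
#' @param covariate_fraction Fraction of subjects with `x = 1`.
#' @param censoring List: `list(type = "administrative", time = ...)` or
#'   `list(type = "random-exponential", rate = ...)`; `time = Inf` disables
#'   censoring.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return Data frame with columns `time`, `status`, `x` and attribute
#'   `truth` (a list with `beta0`, `beta1`, `censoring_fraction`).
#' @export
simulate_censored_survival <- function(n, beta0, beta1,
                                       covariate_fraction = 0.5,
                                       censoring = list(type = "administrative",
                                                        time = Inf),
                                       seed = 1) {
  stopifnot(n >= 1, covariate_fraction > 0, covariate_fraction < 1)
  type <- match.arg(censoring$type, c("administrative", "random-exponential"))
  if (type == "administrative") stopifnot(censoring$time > 0)
  set.seed(seed)
  n1 <- round(n * covariate_fraction)
  x <- sample(c(rep(1L, n1), rep(0L, n - n1)))
  lambda <- exp(beta0 + beta1 * x)
  t_event <- stats::rexp(n, lambda)
  if (type == "administrative") {
    cens_time <- rep(censoring$time, n)
  } else {
    stopifnot(censoring$rate > 0)
    cens_time <- stats::rexp(n, censoring$rate)
  }
  status <- as.integer(t_event <= cens_time)
  time <- pmin(t_event, cens_time)
  out <- data.frame(time = time, status = status, x = x)
  attr(out, "truth") <- list(beta0 = beta0, beta1 = beta1,
                             censoring_fraction = mean(status == 0))
  validate_survival_records(out)
  out
}

#' Simulate a censored adverse-event meta-analysis table
#'
#' Emulates study-level binomial adverse-event counts across the five PD-1 /
#' PD-L1 inhibitors: each study draws a drug, a size from `size_range`, and a
#' binomial count at the drug's true incidence. Counts strictly below the
#' study's reporting cutoff are masked — the count is removed, `censored` set
#' to 1 and the cutoff recorded — emulating selective reporting of only the
#' adverse events whose observed incidence reaches the cutoff.
#'
#' Defaults are sized to echo a realistic rare-event meta-analysis (about 125
#' studies, incidences of a few percent); they are synthetic study conditions,
#' not a reproduction of any published table.
#'
#' @param n_studies Number of studies.
#' @param incidence Named vector of true incidences per drug (names must be
#'   the five known drug labels).
#' @param size_range Integer range of study sizes (uniform draw).
#' @param cutoff Reporting cutoff rule: a fixed nonnegative integer (0
#'   disables censoring) or `list(fraction = f)` for
#'   `max(1, ceiling(f * n))` per study.
#' @param seed Integer seed.
#' @return Data frame with columns `study`, `drug`, `n`, `count`, `censored`,
#'   `cutoff` and attribute `truth` (incidences and the realized censoring
#'   fraction).
#' @export
simulate_ae_meta <- function(n_studies = 125,
                             incidence = c(Nivolumab = 0.03,
                                           Pembrolizumab = 0.04,
                                           Atezolizumab = 0.02,
                                           Avelumab = 0.015,
                                           Durvalumab = 0.025),
                             size_range = c(20, 500),
                             cutoff = 2,
                             seed = 1) {
  stopifnot(n_studies >= 1, all(incidence > 0), all(incidence < 1))
  if (is.null(names(incidence)) || !all(names(incidence) %in% AE_DRUGS)) {
    stop("incidence must be named by the known drug labels", call. = FALSE)
  }
  set.seed(seed)
  drug <- sample(names(incidence), n_studies, replace = TRUE)
  n <- sample(seq(size_range[1], size_range[2]), n_studies, replace = TRUE)
  count <- stats::rbinom(n_studies, n, incidence[drug])
  cut_i <- if (is.list(cutoff)) {
    pmax(1L, as.integer(ceiling(cutoff$fraction * n)))
  } else {
    rep(as.integer(cutoff), n_studies)
  }
  censored <- as.integer(cut_i > 0 & count < cut_i)
  out <- data.frame(
    study = paste0("S", seq_len(n_studies)),
    drug = drug,
    n = n,
    count = ifelse(censored == 1, NA_integer_, count),
    censored = censored,
    cutoff = ifelse(censored == 1, cut_i, NA_integer_)
  )
  attr(out, "truth") <- list(incidence = incidence,
                             censoring_fraction = mean(censored),
                             full_counts = count)
  validate_ae_records(out)
  out
}

#' Parameter-recovery harness
#'
#' Refits a model on independently generated synthetic datasets and reports,
#' per parameter, the mean bias of the posterior mean and the fraction of
#' central credible intervals covering the generating truth. Replicate seeds
#' are derived from `seed` by a counter offset so replicates are independent
#' but the whole harness is reproducible.
#'
#' @param generator Function `(rep_seed) -> dataset` whose result carries a
#'   `truth` attribute (a list of true parameter values named as the fitter
#'   names them).
#' @param fitter Function `(dataset) -> censdev_fit` (or any object with a
#'   `summary` data frame holding `parameter`, `mean`, `q2.5`, `q97.5`).
#' @param n_reps Number of replicates (>= 10).
#' @param parameters Character vector of parameter names to score.
#' @param coverage_level Nominal central credible level (fixed at the 2.5/97.5
#'   summary quantiles; retained for reporting).
#' @param seed Base seed.
#' @return List with `bias` and `coverage` (named per parameter), `n_fail`,
#'   and the per-replicate estimates. More than 20\% failed replicates is an
#'   error; individual failures are recorded and skipped.
#' @export
recovery_harness <- function(generator, fitter, n_reps = 40,
                             parameters, coverage_level = 0.95, seed = 1) {
  stopifnot(n_reps >= 10)
  est <- matrix(NA_real_, n_reps, length(parameters),
                dimnames = list(NULL, parameters))
  lo <- hi <- truth_m <- est
  failures <- character(0)
  for (r in seq_len(n_reps)) {
    rep_seed <- seed + 1000L * r
    res <- tryCatch({
      dat <- generator(rep_seed)
      truth <- attr(dat, "truth")
      fit <- fitter(dat)
      sm <- fit$summary
      list(sm = sm, truth = truth)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0("rep ", r, ": ", conditionMessage(res)))
      next
    }
    for (p in parameters) {
      row <- res$sm[res$sm$parameter == p, ]
      if (nrow(row) != 1 || is.null(res$truth[[p]])) {
        stop("parameter '", p, "' missing from fit summary or truth",
             call. = FALSE)
      }
      est[r, p] <- row$mean
      lo[r, p] <- row$q2.5
      hi[r, p] <- row$q97.5
      truth_m[r, p] <- res$truth[[p]]
    }
  }
  if (length(failures) > 0.2 * n_reps) {
    stop("recovery harness: ", length(failures), "/", n_reps,
         " replicates failed:\n", paste(failures, collapse = "\n"),
         call. = FALSE)
  }
  ok <- stats::complete.cases(est)
  bias <- colMeans(est[ok, , drop = FALSE] - truth_m[ok, , drop = FALSE])
  coverage <- colMeans(lo[ok, , drop = FALSE] <= truth_m[ok, , drop = FALSE] &
                         truth_m[ok, , drop = FALSE] <= hi[ok, , drop = FALSE])
  list(bias = bias, coverage = coverage, n_fail = length(failures),
       failures = failures, estimates = est, lower = lo, upper = hi,
       coverage_level = coverage_level)
}
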