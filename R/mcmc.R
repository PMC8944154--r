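#' MCMC sampling configuration
#'
#' Defaults replicate the sampling protocol used throughout the package's
#' worked survival example: 3 parallel chains, 30,000 burn-in iterations,
#' 10,000 saved draws per chain with thinning by 3.
#'
#' @param n_chains Number of chains (>= 1; >= 2 for R-hat).
#' @param n_burnin Burn-in iterations per chain; proposal step sizes adapt
#'   only during this phase.
#' @param n_saved Saved draws per chain after burn-in.
#' @param thin Thinning interval.
#' @param seed Base seed; chain `c` runs under `seed + c`.
#' @param target_accept Target acceptance rate for the per-coordinate
#'   random-walk adaptation (0.44 is the scalar-update optimum).
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 3, n_burnin = 30000, n_saved = 10000,
                        thin = 3, seed = 1, target_accept = 0.44) {
  stopifnot(n_chains >= 1, n_burnin >= 0, n_saved >= 1, thin >= 1,
            target_accept > 0, target_accept < 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_burnin = as.integer(n_burnin),
                 n_saved = as.integer(n_saved),
                 thin = as.integer(thin),
                 seed = as.integer(seed),
                 target_accept = target_accept),
            class = "mcmc_config")
}

#' Adaptive random-walk Metropolis-within-Gibbs sampler
#'
#' Draws posterior samples by updating one parameter at a time with a
#' Gaussian random-walk proposal on an unconstrained scale (log for positive
#' parameters, scaled logit for bounded ones), including the transform's
#' Jacobian in the target. Step sizes adapt toward `target_accept` by a
#' Robbins–Monro recursion during burn-in only and are frozen afterwards, so
#' the post-burn-in chain is a fixed-kernel Markov chain. Chain `c` is run
#' under seed `config$seed + c`; identical inputs and seeds give bit-identical
#' output.
#'
#' The target can be supplied two ways:
#' \itemize{
#'   \item `log_posterior(theta)`: joint log posterior (likelihood + prior) on
#'     the constrained scale;
#'   \item `log_lik_terms(theta, idx)`: per-observation log-likelihood terms
#'     (restricted to indices `idx` when given), plus optionally `log_prior`
#'     (defaults to the sum of the marginal priors) and `deps`, a list mapping
#'     each parameter to the observation indices its value affects. Updates
#'     then recompute only affected terms, which is what makes saturated
#'     many-parameter models affordable.
#' }
#'
#' @param log_posterior Function of the named parameter vector, or `NULL`
#'   when the structured form is used.
#' @param priors Named list of [priors] (`prior_spec` objects), one per
#'   parameter; defines parameter order, supports/transforms and default
#'   initial values (prior medians).
#' @param init Optional named numeric vector of initial values on the
#'   constrained scale.
#' @param config An [mcmc_config()].
#' @param log_lik_terms,log_prior,deps Structured-target pieces (see above).
#' @param log_prior_delta Optional function `(theta, theta_new, j)` returning
#'   the change in the joint log prior when only parameter `j` changes; lets
#'   hierarchical models with many parameters avoid re-evaluating the full
#'   prior at every coordinate update. Must agree with `log_prior`.
#' @param n_terms Number of likelihood terms when `log_lik_terms` is used.
#' @return A `posterior_samples` object: `draws` array of dimension
#'   (chain, draw, parameter) on the constrained scale, parameter names,
#'   transforms, per-chain acceptance rates, frozen step sizes, the number of
#'   non-finite proposal evaluations rejected, and a config echo.
#' @examples
#' # conjugate Beta(1,1) + Binomial(10, p), y = 3: posterior is Beta(4, 8)
#' lp <- function(theta) dbinom(3, 10, theta[["p"]], log = TRUE)
#' fit <- run_mcmc(lp, priors = list(p = prior_beta(1, 1)),
#'                 config = mcmc_config(n_chains = 2, n_burnin = 500,
#'                                      n_saved = 500, thin = 1, seed = 7))
#' mean(fit$draws[, , "p"])  # close to 4/12
#' @export
run_mcmc <- function(log_posterior = NULL, priors, init = NULL,
                     config = mcmc_config(),
                     log_lik_terms = NULL, log_prior = NULL, deps = NULL,
                     log_prior_delta = NULL, n_terms = NULL) {
  stopifnot(is.list(priors), length(priors) >= 1,
            !is.null(names(priors)), all(nzchar(names(priors))))
  if (!all(vapply(priors, inherits, logical(1), "prior_spec"))) {
    stop("every element of 'priors' must be a prior_spec", call. = FALSE)
  }
  pnames <- names(priors)
  P <- length(priors)
  structured <- !is.null(log_lik_terms)
  if (!structured && is.null(log_posterior)) {
    stop("supply either log_posterior or log_lik_terms", call. = FALSE)
  }
  transforms <- lapply(priors, function(pr) support_transform(pr$support))

  if (is.null(init)) {
    init <- vapply(priors, `[[`, numeric(1), "median")
    names(init) <- pnames
  } else {
    if (is.null(names(init)) || !setequal(names(init), pnames)) {
      stop("init must be a named vector covering every parameter", call. = FALSE)
    }
    init <- init[pnames]
  }

  if (structured) {
    if (is.null(log_prior)) {
      log_prior <- function(theta) {
        s <- 0
        for (j in seq_len(P)) s <- s + priors[[j]]$log_density(theta[[j]])
        s
      }
    }
    if (is.null(deps)) deps <- vector("list", P)
    if (!is.null(names(deps))) deps <- deps[pnames]
  }

  # target pieces at a parameter vector, constrained scale, prior included
  eval_full <- function(theta) {
    if (structured) {
      tt <- log_lik_terms(theta, NULL)
      list(terms = tt, lp = log_prior(theta),
           total = sum(tt) + log_prior(theta))
    } else {
      v <- log_posterior(theta)
      list(terms = NULL, lp = NULL, total = v)
    }
  }

  f0 <- eval_full(as.list(init))
  if (!is.finite(f0$total)) {
    stop("log posterior is not finite at the initial values", call. = FALSE)
  }

  n_iter <- config$n_burnin + config$n_saved * config$thin
  draws <- array(NA_real_,
                 dim = c(config$n_chains, config$n_saved, P),
                 dimnames = list(NULL, NULL, pnames))
  accept <- matrix(0, config$n_chains, P, dimnames = list(NULL, pnames))
  steps <- matrix(NA_real_, config$n_chains, P, dimnames = list(NULL, pnames))
  n_nonfinite <- 0L

  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch)
    theta <- as.list(init)
    z <- numeric(P)
    ljac <- numeric(P)
    for (j in seq_len(P)) {
      z[j] <- transforms[[j]]$fwd(init[[j]])
      ljac[j] <- transforms[[j]]$ljac(z[j])
    }
    cur <- eval_full(theta)
    cur_terms <- cur$terms
    cur_lp <- cur$lp
    cur_total <- cur$total
    ls <- rep(log(0.5), P)
    acc_count <- numeric(P)
    saved <- 0L
    post_burn <- 0L

    for (t in seq_len(n_iter)) {
      eps <- stats::rnorm(P)
      lu <- log(stats::runif(P))
      adapting <- t <= config$n_burnin
      gam <- if (adapting) min(0.5, t^-0.6) else 0
      for (j in seq_len(P)) {
        zj_new <- z[j] + exp(ls[j]) * eps[j]
        th_new <- transforms[[j]]$inv(zj_new)
        lj_new <- transforms[[j]]$ljac(zj_new)
        theta_new <- theta
        theta_new[[j]] <- th_new
        if (structured) {
          idx <- deps[[j]]
          new_terms <- log_lik_terms(theta_new, idx)
          if (is.null(log_prior_delta)) {
            lp_new <- log_prior(theta_new)
            dprior <- lp_new - cur_lp
          } else {
            dprior <- log_prior_delta(theta, theta_new, j)
          }
          if (anyNA(new_terms) || is.na(dprior)) {
            n_nonfinite <- n_nonfinite + 1L
            logr <- -Inf
          } else {
            old_part <- if (is.null(idx)) sum(cur_terms) else sum(cur_terms[idx])
            logr <- (sum(new_terms) - old_part) + dprior +
              (lj_new - ljac[j])
          }
        } else {
          v_new <- log_posterior(theta_new)
          if (is.na(v_new)) {
            n_nonfinite <- n_nonfinite + 1L
            logr <- -Inf
          } else {
            logr <- (v_new + lj_new) - (cur_total + ljac[j])
          }
        }
        if (is.nan(logr)) { n_nonfinite <- n_nonfinite + 1L; logr <- -Inf }
        if (lu[j] < logr) {
          z[j] <- zj_new
          ljac[j] <- lj_new
          theta <- theta_new
          if (structured) {
            if (is.null(deps[[j]])) cur_terms <- new_terms
            else cur_terms[deps[[j]]] <- new_terms
            cur_lp <- if (is.null(log_prior_delta)) lp_new else cur_lp + dprior
          } else {
            cur_total <- v_new
          }
          if (!adapting) acc_count[j] <- acc_count[j] + 1
        }
        if (adapting) {
          alpha <- min(1, exp(logr))
          ls[j] <- ls[j] + gam * (alpha - config$target_accept)
        }
      }
      if (!adapting) {
        post_burn <- post_burn + 1L
        if (post_burn %% config$thin == 0L) {
          saved <- saved + 1L
          draws[ch, saved, ] <- unlist(theta, use.names = FALSE)
        }
      }
    }
    accept[ch, ] <- acc_count / (n_iter - config$n_burnin)
    steps[ch, ] <- exp(ls)
  }

  structure(list(draws = draws, parameters = pnames, priors = priors,
                 transforms = transforms, config = config,
                 acceptance = accept, step_sizes = steps,
                 n_nonfinite = n_nonfinite),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("<posterior_samples> ", dim(x$draws)[1], " chains x ", dim(x$draws)[2],
      " draws x ", dim(x$draws)[3], " parameters (",
      paste(x$parameters, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Posterior summary table
#'
#' Mean, standard deviation, central quantiles and split-chain R-hat per
#' parameter. Each chain is split in half before computing the
#' between/within-variance ratio, which also flags non-stationarity within a
#' chain. Exactly constant chains get R-hat 1 and a degenerate flag.
#'
#' @param samples A `posterior_samples` object from [run_mcmc()].
#' @return A data frame with one row per parameter: `mean`, `sd`, `q2.5`,
#'   `q50`, `q97.5`, `rhat`, `degenerate`.
#' @export
posterior_summary <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"))
  dm <- dim(samples$draws)
  if (dm[2] == 0) stop("no saved draws to summarize", call. = FALSE)
  out <- lapply(seq_len(dm[3]), function(p) {
    x <- samples$draws[, , p, drop = FALSE]
    pooled <- as.vector(x)
    qs <- stats::quantile(pooled, c(0.025, 0.5, 0.975), names = FALSE)
    degenerate <- stats::sd(pooled) == 0
    data.frame(parameter = samples$parameters[p],
               mean = mean(pooled), sd = stats::sd(pooled),
               q2.5 = qs[1], q50 = qs[2], q97.5 = qs[3],
               rhat = if (degenerate) 1.0 else split_rhat(x[, , 1, drop = FALSE]),
               degenerate = degenerate)
  })
  do.call(rbind, out)
}

split_rhat <- function(x) {
  # x: chains x draws (x 1); split each chain in half
  n_ch <- dim(x)[1]; n_dr <- dim(x)[2]
  if (n_dr < 4) return(NA_real_)
  half <- floor(n_dr / 2)
  chains <- list()
  for (c in seq_len(n_ch)) {
    chains[[length(chains) + 1]] <- x[c, seq_len(half), 1]
    chains[[length(chains) + 1]] <- x[c, seq(half + 1, 2 * half), 1]
  }
  m <- length(chains); n <- half
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1.0)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Gaussian kernel density of a posterior parameter
#'
#' Pooled-chain kernel density with Silverman's bandwidth, the curve behind
#' density comparison plots of posterior coefficients and deviances.
#'
#' @param samples A `posterior_samples` object.
#' @param parameter Parameter name.
#' @param n_grid Number of grid points.
#' @return List with `grid`, `height` and `bw`; heights integrate to 1 on the
#'   grid to within 1e-3.
#' @export
kernel_density <- function(samples, parameter, n_grid = 512) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (!parameter %in% samples$parameters) {
    stop("unknown parameter '", parameter, "'", call. = FALSE)
  }
  x <- as.vector(samples$draws[, , parameter])
  if (length(x) < 100) {
    stop("kernel_density needs at least 100 draws", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("draws are constant; kernel density is a degenerate spike",
         call. = FALSE)
  }
  d <- stats::density(x, bw = "nrd0", n = n_grid)
  list(grid = d$x, height = d$y, bw = d$bw)
}

#' Write / read posterior draws as long-format CSV
#'
#' Columns `chain`, `iteration`, `parameter`, `value`, readable by external
#' diagnostics tooling; `read_posterior_csv()` reconstructs the draw array.
#'
#' @param samples A `posterior_samples` object.
#' @param path File path.
#' @return `write_posterior_csv()` returns `path` invisibly;
#'   `read_posterior_csv()` a `posterior_samples`-like object (draws and
#'   parameter names only).
#' @export
write_posterior_csv <- function(samples, path) {
  dm <- dim(samples$draws)
  long <- expand.grid(chain = seq_len(dm[1]), iteration = seq_len(dm[2]),
                      parameter = samples$parameters,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$value <- as.vector(samples$draws)
  long <- long[order(long$parameter, long$chain, long$iteration), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_posterior_csv
#' @export
read_posterior_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chain", "iteration", "parameter", "value")
  if (!all(need %in% names(long))) {
    stop("posterior CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  pnames <- unique(long$parameter)
  n_ch <- max(long$chain); n_dr <- max(long$iteration)
  draws <- array(NA_real_, dim = c(n_ch, n_dr, length(pnames)),
                 dimnames = list(NULL, NULL, pnames))
  draws[cbind(long$chain, long$iteration, match(long$parameter, pnames))] <-
    long$value
  structure(list(draws = draws, parameters = pnames, priors = NULL,
                 transforms = NULL, config = NULL),
            class = "posterior_samples")
}

#' Plug-in posterior point estimate on the unconstrained scale
#'
#' The posterior mean taken on each parameter's unconstrained scale and
#' mapped back, which keeps deviance plug-in estimates invariant to how
#' constrained parameters are parameterized.
#'
#' @param samples A `posterior_samples` object produced by [run_mcmc()]
#'   (transforms must be present).
#' @return Named numeric vector on the constrained scale.
#' @export
posterior_plugin_estimate <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (is.null(samples$transforms)) {
    stop("samples carry no transforms; plug-in estimate unavailable",
         call. = FALSE)
  }
  P <- length(samples$parameters)
  out <- numeric(P)
  for (j in seq_len(P)) {
    tr <- samples$transforms[[j]]
    out[j] <- tr$inv(mean(tr$fwd(as.vector(samples$draws[, , j]))))
  }
  names(out) <- samples$parameters
  out
}
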