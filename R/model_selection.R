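#' Per-observation deviance monitor
#'
#' Evaluates, at every saved posterior draw, each observation's exact
#' deviance contribution \eqn{-2 \log L_i(\theta)}: log densities for
#' observed records and log distribution-function / survivor / interval
#' probabilities for censored ones. Censored observations therefore
#' contribute their true (nonzero) deviance — the correction that makes
#' deviance-based model comparison valid under censoring, in contrast to
#' censoring-indicator devices whose deviance monitor silently assigns
#' censored records a likelihood of 1.
#'
#' @param samples A `posterior_samples` object from [run_mcmc()].
#' @param data A [censored_data()] object.
#' @param model Function mapping a named parameter list (one draw) to the
#'   per-observation [family_spec()] (vector parameters allowed) for `data`.
#' @param count_strict Passed to [censored_loglik_terms()].
#' @return A `deviance_samples` object: `per_obs` (draws x N matrix), `total`,
#'   `obs_part`, `cen_part` per draw, the chain index of each draw, and the
#'   block structure.
#' @export
monitor_deviance <- function(samples, data, model, count_strict = TRUE) {
  stopifnot(inherits(samples, "posterior_samples"),
            inherits(data, "censored_data"))
  dm <- dim(samples$draws)
  n_total <- dm[1] * dm[2]
  per_obs <- matrix(NA_real_, n_total, data$n)
  chain_id <- integer(n_total)
  k <- 0L
  for (ch in seq_len(dm[1])) {
    for (t in seq_len(dm[2])) {
      k <- k + 1L
      theta <- as.list(samples$draws[ch, t, ])
      names(theta) <- samples$parameters
      specs <- model(theta)
      per_obs[k, ] <- -2 * as.numeric(
        censored_loglik_terms(data, specs, count_strict))
      chain_id[k] <- ch
    }
  }
  total <- rowSums(per_obs)
  obs_part <- if (length(data$O)) rowSums(per_obs[, data$O, drop = FALSE]) else
    numeric(n_total)
  cen_idx <- c(data$C, data$I)
  cen_part <- if (length(cen_idx)) rowSums(per_obs[, cen_idx, drop = FALSE]) else
    numeric(n_total)
  structure(list(per_obs = per_obs, total = total, obs_part = obs_part,
                 cen_part = cen_part, chain = chain_id,
                 blocks = list(O = data$O, C = data$C, I = data$I),
                 n_obs = data$n),
            class = "deviance_samples")
}

#' @export
print.deviance_samples <- function(x, ...) {
  cat("<deviance_samples> ", length(x$total), " draws x ", x$n_obs,
      " observations; mean total deviance ", format(mean(x$total)),
      "\n", sep = "")
  invisible(x)
}

#' Observed-only ("wrong focus") deviance diagnostic
#'
#' Per-draw deviance computed from the observed block only, i.e. with every
#' censored observation's contribution replaced by zero. This reproduces what
#' a deviance monitor reports when censoring is handled by an interval
#' indicator whose likelihood is constant 1 — a diagnostic for demonstrating
#' the resulting bias, never an input to model comparison.
#'
#' @param dev A `deviance_samples` object.
#' @return Numeric vector of per-draw observed-block deviances.
#' @export
observed_only_deviance <- function(dev) {
  stopifnot(inherits(dev, "deviance_samples"))
  dev$obs_part
}

plugin_deviance <- function(samples, data, model, count_strict = TRUE) {
  theta_hat <- posterior_plugin_estimate(samples)
  specs <- model(as.list(theta_hat))
  list(theta_hat = theta_hat,
       per_obs = -2 * as.numeric(censored_loglik_terms(data, specs,
                                                       count_strict)))
}

#' Deviance information criterion
#'
#' \eqn{DIC = \bar D + p_D}: the posterior mean deviance plus the effective
#' number of parameters. Two labeled estimators of \eqn{p_D}:
#' \describe{
#'   \item{`"plugin"` (default)}{\eqn{p_D = \bar D - D(\hat\theta)} with
#'     \eqn{\hat\theta} the posterior mean taken on the unconstrained scale
#'     ([posterior_plugin_estimate()]).}
#'   \item{`"variance"`}{half the posterior variance of the deviance,
#'     \eqn{p_D = \mathrm{Var}(D)/2}.}
#' }
#' A negative plug-in \eqn{p_D} (a known pathology when the posterior mean is
#' a poor point summary) is reported as-is with `pd_negative = TRUE`, never
#' clipped.
#'
#' @param dev A `deviance_samples` object from [monitor_deviance()].
#' @param samples The `posterior_samples` the monitor was run on.
#' @param data,model,count_strict As in [monitor_deviance()]; needed to
#'   evaluate the plug-in deviance.
#' @param pd_estimator `"plugin"` or `"variance"`.
#' @return List with `Dbar`, `pD`, `DIC`, `pD_i` (per-observation plug-in
#'   split), `pd_estimator`, `pd_negative`.
#' @export
compute_dic <- function(dev, samples, data, model,
                        pd_estimator = c("plugin", "variance"),
                        count_strict = TRUE) {
  stopifnot(inherits(dev, "deviance_samples"))
  pd_estimator <- match.arg(pd_estimator)
  Dbar <- mean(dev$total)
  plug <- plugin_deviance(samples, data, model, count_strict)
  pD_i <- colMeans(dev$per_obs) - plug$per_obs
  pD <- switch(pd_estimator,
    plugin   = Dbar - sum(plug$per_obs),
    variance = stats::var(dev$total) / 2
  )
  pd_negative <- pD < 0
  if (pd_negative) {
    warning("negative effective number of parameters (pD = ",
            format(pD), "); reported unclipped", call. = FALSE)
  }
  list(Dbar = Dbar, pD = pD, DIC = Dbar + pD, pD_i = pD_i,
       pd_estimator = pd_estimator, pd_negative = pd_negative)
}

#' Penalized expected deviance
#'
#' \eqn{PED = \bar D + p_{opt}}, where the optimism \eqn{p_{opt}} penalizes
#' the double use of the data in \eqn{\bar D}. Two labeled estimators:
#' \describe{
#'   \item{`"asymptotic"` (default)}{\eqn{p_{opt} = 2 \sum_i p_{D,i}} with the
#'     per-observation plug-in split of \eqn{p_D}; exact in the large-sample
#'     Gaussian limit.}
#'   \item{`"importance"`}{a leave-one-out importance-sampling estimator:
#'     for observation i, draws are reweighted by
#'     \eqn{w_t \propto 1/f(y_i \mid \theta_t) = \exp\{d_i(\theta_t)/2\}}
#'     (self-normalized), which targets the posterior without observation i;
#'     \eqn{p_{opt,i}} is the reweighted minus the plain posterior mean of
#'     \eqn{d_i}. Observations whose importance weights collapse (effective
#'     sample size below 5\% of draws) fall back to the asymptotic
#'     \eqn{2 p_{D,i}} with a warning.}
#' }
#'
#' @inheritParams compute_dic
#' @param popt_estimator `"asymptotic"` or `"importance"`.
#' @return List with `Dbar`, `p_opt`, `PED`, `popt_estimator`,
#'   `n_weight_fallback` (importance estimator only).
#' @export
compute_ped <- function(dev, samples, data, model,
                        popt_estimator = c("asymptotic", "importance"),
                        count_strict = TRUE) {
  stopifnot(inherits(dev, "deviance_samples"))
  popt_estimator <- match.arg(popt_estimator)
  Dbar <- mean(dev$total)
  plug <- plugin_deviance(samples, data, model, count_strict)
  pD_i <- colMeans(dev$per_obs) - plug$per_obs
  n_fallback <- 0L
  if (popt_estimator == "asymptotic") {
    p_opt <- 2 * sum(pD_i)
  } else {
    T_dr <- nrow(dev$per_obs)
    p_opt_i <- numeric(dev$n_obs)
    for (i in seq_len(dev$n_obs)) {
      d_i <- dev$per_obs[, i]
      lw <- d_i / 2
      lw <- lw - max(lw)
      w <- exp(lw)
      w <- w / sum(w)
      ess <- 1 / sum(w^2)
      if (ess < 0.05 * T_dr) {
        n_fallback <- n_fallback + 1L
        p_opt_i[i] <- 2 * pD_i[i]
      } else {
        p_opt_i[i] <- sum(w * d_i) - mean(d_i)
      }
    }
    if (n_fallback > 0) {
      warning(n_fallback, " observation(s) had degenerate importance weights;",
              " fell back to the asymptotic per-observation penalty",
              call. = FALSE)
    }
    p_opt <- sum(p_opt_i)
  }
  list(Dbar = Dbar, p_opt = p_opt, PED = Dbar + p_opt,
       popt_estimator = popt_estimator, n_weight_fallback = n_fallback)
}

#' Model comparison report
#'
#' Collects fitted models into one table with the five deviance-based
#' statistics — mean deviance, effective number of parameters, DIC, optimism
#' and PED — plus the estimator labels, and flags the minimum-DIC and
#' minimum-PED rows. All fits must be on the same dataset.
#'
#' @param fits Named list of fit objects (each carrying `dic`, `ped` and a
#'   `data_fingerprint`, as returned by the `fit_*` presets).
#' @return A `comparison_report`: a data frame with columns `model`, `Dbar`,
#'   `pD`, `DIC`, `p_opt`, `PED`, `pd_estimator`, `popt_estimator`,
#'   `min_DIC`, `min_PED`.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    names(fits) <- paste0("model_", seq_along(fits))
  }
  fps <- vapply(fits, function(f) f$data_fingerprint, character(1))
  if (length(unique(fps)) != 1) {
    stop("fits were made on different datasets; comparison is not meaningful",
         call. = FALSE)
  }
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(model = nm, Dbar = f$dic$Dbar, pD = f$dic$pD, DIC = f$dic$DIC,
               p_opt = f$ped$p_opt, PED = f$ped$PED,
               pd_estimator = f$dic$pd_estimator,
               popt_estimator = f$ped$popt_estimator,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep$min_DIC <- rep$DIC == min(rep$DIC)
  rep$min_PED <- rep$PED == min(rep$PED)
  class(rep) <- c("comparison_report", "data.frame")
  rep
}

#' @export
print.comparison_report <- function(x, digits = 2, ...) {
  cat(format_report(x, digits = digits), sep = "\n")
  invisible(x)
}

#' Render or write a comparison report
#'
#' `format_report()` gives an aligned text table with the column order
#' mean deviance, pD, DIC, p_opt, PED; `write_report_csv()` writes the same
#' columns as CSV.
#'
#' @param report A `comparison_report` from [compare_models()].
#' @param digits Digits for the text table.
#' @param path Output file for the CSV.
#' @return `format_report()`: character vector of lines;
#'   `write_report_csv()`: `path`, invisibly.
#' @export
format_report <- function(report, digits = 2) {
  df <- as.data.frame(report)
  num <- c("Dbar", "pD", "DIC", "p_opt", "PED")
  for (cc in num) df[[cc]] <- formatC(df[[cc]], format = "f", digits = digits)
  df$model <- ifelse(report$min_DIC, paste0(df$model, " *DIC"), df$model)
  df$model <- ifelse(report$min_PED, paste0(df$model, " *PED"), df$model)
  cols <- c("model", num)
  widths <- vapply(cols, function(cc) max(nchar(c(cc, df[[cc]]))), numeric(1))
  fmt_row <- function(vals) {
    paste(mapply(formatC, vals, width = widths, flag = "-"), collapse = "  ")
  }
  c(fmt_row(cols), fmt_row(rep("-", length(cols))),
    vapply(seq_len(nrow(df)),
           function(r) fmt_row(unlist(df[r, cols])), character(1)))
}

#' @rdname format_report
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
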