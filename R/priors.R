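#' Prior specifications
#'
#' Marginal prior constructors for model parameters. Each prior carries its
#' support, which determines the unconstrained transform the sampler uses
#' (identity on the real line, log for positive parameters, scaled logit for
#' bounded ones), its log density on the constrained scale, and its median
#' (the sampler's default initial value).
#'
#' @param mean,sd Normal location and spread (`sd > 0`).
#' @param scale Half-Cauchy scale (`> 0`); support \eqn{(0, \infty)}.
#' @param a,b Beta shapes (`> 0`); support \eqn{(0, 1)}.
#' @param lo,hi Uniform bounds (`lo < hi`).
#' @return A `prior_spec` object.
#' @examples
#' pr <- prior_halfcauchy(1)
#' pr$median  # the half-Cauchy median equals its scale
#' @name priors
NULL

new_prior <- function(kind, support, log_density, median, hyper) {
  structure(list(kind = kind, support = support, log_density = log_density,
                 median = median, hyper = hyper),
            class = "prior_spec")
}

#' @rdname priors
#' @export
prior_normal <- function(mean = 0, sd = 1) {
  stopifnot(sd > 0)
  new_prior("normal", c(-Inf, Inf),
            function(x) stats::dnorm(x, mean, sd, log = TRUE),
            mean, c(mean = mean, sd = sd))
}

#' @rdname priors
#' @export
prior_halfcauchy <- function(scale = 1) {
  stopifnot(scale > 0)
  new_prior("half-cauchy", c(0, Inf),
            function(x) ifelse(x > 0,
                               log(2) + stats::dcauchy(x, 0, scale, log = TRUE),
                               -Inf),
            scale, c(scale = scale))
}

#' @rdname priors
#' @export
prior_beta <- function(a = 1, b = 1) {
  stopifnot(a > 0, b > 0)
  new_prior("beta", c(0, 1),
            function(x) stats::dbeta(x, a, b, log = TRUE),
            stats::qbeta(0.5, a, b), c(a = a, b = b))
}

#' @rdname priors
#' @export
prior_uniform <- function(lo = 0, hi = 1) {
  stopifnot(lo < hi)
  new_prior("uniform", c(lo, hi),
            function(x) stats::dunif(x, lo, hi, log = TRUE),
            (lo + hi) / 2, c(lo = lo, hi = hi))
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec> ", x$kind, "(",
      paste(names(x$hyper), x$hyper, sep = " = ", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# Transform bundle for a support interval: to_unconstrained, to_constrained,
# and the log-Jacobian of the constrained value w.r.t. the unconstrained one.
support_transform <- function(support) {
  lo <- support[1]; hi <- support[2]
  if (is.infinite(lo) && is.infinite(hi)) {
    list(fwd = identity, inv = identity, ljac = function(z) 0)
  } else if (is.finite(lo) && is.infinite(hi)) {
    list(fwd = function(x) log(x - lo),
         inv = function(z) lo + exp(z),
         ljac = function(z) z)
  } else {
    width <- hi - lo
    list(fwd = function(x) stats::qlogis((x - lo) / width),
         inv = function(z) lo + width * stats::plogis(z),
         ljac = function(z) log(width) + stats::plogis(z, log.p = TRUE) +
           stats::plogis(-z, log.p = TRUE))
  }
}
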