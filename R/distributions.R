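#' Parametric outcome families
#'
#' A `family_spec` bundles a distribution family with its parameter values and
#' is the unit every likelihood routine in the package consumes. All
#' evaluations happen in log space so that censored-data likelihood terms
#' (log densities, log distribution functions, log survivor functions) never
#' go through an exp-then-log round trip.
#'
#' Supported families and their parameters:
#' \describe{
#'   \item{`exponential`}{`rate` \eqn{\lambda > 0}; survivor
#'     \eqn{S(y) = e^{-\lambda y}}.}
#'   \item{`weibull`}{`shape` \eqn{k > 0}, `scale` \eqn{s > 0}, with
#'     \eqn{S(y) = \exp\{-(y/s)^k\}} (the parameterization of
#'     [stats::pweibull()]).}
#'   \item{`normal`}{`mean`, `sd` \eqn{> 0}.}
#'   \item{`lognormal`}{`meanlog`, `sdlog` \eqn{> 0}.}
#'   \item{`loglogistic`}{`shape` \eqn{k > 0}, `scale` \eqn{s > 0}, with
#'     \eqn{F(y) = 1 / (1 + (y/s)^{-k})}.}
#'   \item{`binomial`}{`size` \eqn{n}, `prob` \eqn{p \in (0,1)}.}
#'   \item{`betabinomial`}{`size` \eqn{n}, `shape1` \eqn{a > 0},
#'     `shape2` \eqn{b > 0}; the binomial with a Beta(a, b)-mixed success
#'     probability, evaluated through log-gamma functions.}
#' }
#'
#' Parameters may be vectors (recycled against the outcome vector), which is
#' how covariate-dependent models hand one resolved parameter per observation
#' to the likelihood in a single call.
#'
#' @param family Family name, one of `"exponential"`, `"weibull"`, `"normal"`,
#'   `"lognormal"`, `"loglogistic"`, `"binomial"`, `"betabinomial"`.
#' @param ... Named numeric parameters as listed above.
#' @return An object of class `family_spec` with elements `family`, `params`
#'   and `support` (`"continuous-positive"`, `"continuous-real"` or
#'   `"integer-count"`).
#' @examples
#' sp <- family_spec("exponential", rate = 1)
#' log_density(sp, 1)   # -1
#' log_survival(sp, 50) # -50, no underflow
#' @export
family_spec <- function(family, ...) {
  family <- match.arg(family, c(
    "exponential", "weibull", "normal", "lognormal",
    "loglogistic", "binomial", "betabinomial"
  ))
  params <- list(...)
  required <- switch(family,
    exponential  = "rate",
    weibull      = c("shape", "scale"),
    normal       = c("mean", "sd"),
    lognormal    = c("meanlog", "sdlog"),
    loglogistic  = c("shape", "scale"),
    binomial     = c("size", "prob"),
    betabinomial = c("size", "shape1", "shape2")
  )
  missing <- setdiff(required, names(params))
  if (length(missing)) {
    stop("family_spec('", family, "') is missing parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  params <- params[required]
  for (nm in names(params)) {
    if (!is.numeric(params[[nm]]) || anyNA(params[[nm]])) {
      stop("parameter '", nm, "' must be numeric and non-missing", call. = FALSE)
    }
  }
  chk_pos <- function(nm) {
    if (any(params[[nm]] <= 0)) {
      stop("parameter '", nm, "' must be > 0", call. = FALSE)
    }
  }
  switch(family,
    exponential  = chk_pos("rate"),
    weibull      = { chk_pos("shape"); chk_pos("scale") },
    normal       = chk_pos("sd"),
    lognormal    = chk_pos("sdlog"),
    loglogistic  = { chk_pos("shape"); chk_pos("scale") },
    binomial     = {
      if (any(params$size < 1 | params$size != round(params$size)))
        stop("parameter 'size' must be a positive integer", call. = FALSE)
      if (any(params$prob <= 0 | params$prob >= 1))
        stop("parameter 'prob' must lie in (0, 1)", call. = FALSE)
    },
    betabinomial = {
      if (any(params$size < 1 | params$size != round(params$size)))
        stop("parameter 'size' must be a positive integer", call. = FALSE)
      chk_pos("shape1"); chk_pos("shape2")
    }
  )
  support <- switch(family,
    exponential = , weibull = , lognormal = , loglogistic = "continuous-positive",
    normal = "continuous-real",
    binomial = , betabinomial = "integer-count"
  )
  structure(list(family = family, params = params, support = support),
            class = "family_spec")
}

#' @export
print.family_spec <- function(x, ...) {
  pp <- vapply(x$params, function(v) {
    if (length(v) > 1) sprintf("<%d values>", length(v)) else format(v)
  }, character(1))
  cat("<family_spec> ", x$family, "(",
      paste(names(pp), pp, sep = " = ", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

is_count_family <- function(spec) spec$support == "integer-count"

# validation-free constructor for hot loops (parameters already vetted by the
# model builder; sampler transforms keep them in range)
unsafe_spec <- function(family, params, support) {
  structure(list(family = family, params = params, support = support),
            class = "family_spec")
}

# log pmf of the beta-binomial through log-gamma; vectorized over y and params
lbetabinom <- function(y, size, a, b) {
  lchoose(size, y) + lbeta(y + a, size - y + b) - lbeta(a, b)
}

# log-sum-exp along rows of a list of log terms built by vapply
lse2 <- function(la, lb) {
  m <- pmax(la, lb)
  out <- m + log(exp(la - m) + exp(lb - m))
  out[la == -Inf & lb == -Inf] <- -Inf
  out
}

# cumulative log-probability for count families by explicit summation
# over 0..floor(y); sizes here are study-level so the sum is short.
count_log_cdf <- function(spec, y, lower_tail = TRUE) {
  p <- spec$params
  if (spec$family == "binomial") {
    return(stats::pbinom(floor(y), p$size, p$prob,
                         lower.tail = lower_tail, log.p = TRUE))
  }
  n_obs <- max(length(y), lengths(p))
  y <- rep_len(y, n_obs)
  pr <- lapply(p, rep_len, n_obs)
  out <- numeric(n_obs)
  for (i in seq_len(n_obs)) {
    k_hi <- floor(y[i])
    size <- pr$size[i]
    if (lower_tail && k_hi < 0) { out[i] <- -Inf; next }
    if (!lower_tail && k_hi >= size) { out[i] <- -Inf; next }
    ks <- if (lower_tail) seq(0, min(k_hi, size)) else seq(k_hi + 1, size)
    lp <- lbetabinom(ks, size, pr$shape1[i], pr$shape2[i])
    m <- max(lp)
    out[i] <- min(m + log(sum(exp(lp - m))), 0)
  }
  out
}

#' Log density / log distribution / log survivor evaluation
#'
#' The three building blocks of the censored-data likelihood: `log_density()`
#' is the log density (or log pmf) at `y`, `log_cdf()` is \eqn{\log F(y)}
#' (for count families \eqn{F(y) = P(Y \le \lfloor y \rfloor)}), and
#' `log_survival()` is \eqn{\log\{1 - F(y)\}} computed by a dedicated upper-tail
#' form so it stays accurate when \eqn{F(y)} is close to 1 — e.g. an
#' exponential with rate 1 at \eqn{y = 50} returns exactly \eqn{-50} rather
#' than underflowing to \eqn{-\infty}.
#'
#' @param spec A [family_spec()].
#' @param y Outcome value(s); recycled against vector parameters.
#' @return Numeric vector of log probabilities / log densities.
#' @export
log_density <- function(spec, y) {
  stopifnot(inherits(spec, "family_spec"))
  p <- spec$params
  check_support(spec, y)
  switch(spec$family,
    exponential  = stats::dexp(y, p$rate, log = TRUE),
    weibull      = stats::dweibull(y, p$shape, p$scale, log = TRUE),
    normal       = stats::dnorm(y, p$mean, p$sd, log = TRUE),
    lognormal    = stats::dlnorm(y, p$meanlog, p$sdlog, log = TRUE),
    loglogistic  = {
      # f(y) = (k/s) (y/s)^{k-1} / (1 + (y/s)^k)^2
      lz <- p$shape * (log(y) - log(p$scale))
      log(p$shape) - log(y) + lz - 2 * log1pexp(lz)
    },
    binomial     = stats::dbinom(y, p$size, p$prob, log = TRUE),
    betabinomial = lbetabinom(y, p$size, p$shape1, p$shape2)
  )
}

#' @rdname log_density
#' @export
log_cdf <- function(spec, y) {
  stopifnot(inherits(spec, "family_spec"))
  p <- spec$params
  switch(spec$family,
    exponential  = stats::pexp(y, p$rate, log.p = TRUE),
    weibull      = stats::pweibull(y, p$shape, p$scale, log.p = TRUE),
    normal       = stats::pnorm(y, p$mean, p$sd, log.p = TRUE),
    lognormal    = stats::plnorm(y, p$meanlog, p$sdlog, log.p = TRUE),
    loglogistic  = {
      # F(y) = 1/(1 + (y/s)^{-k}); log F = -log1p(exp(-k log(y/s)))
      out <- ifelse(y <= 0, -Inf,
                    -log1pexp(-p$shape * (log(pmax(y, .Machine$double.xmin)) -
                                            log(p$scale))))
      out
    },
    binomial     = ,
    betabinomial = count_log_cdf(spec, y, lower_tail = TRUE)
  )
}

#' @rdname log_density
#' @export
log_survival <- function(spec, y) {
  stopifnot(inherits(spec, "family_spec"))
  p <- spec$params
  switch(spec$family,
    exponential  = stats::pexp(y, p$rate, lower.tail = FALSE, log.p = TRUE),
    weibull      = stats::pweibull(y, p$shape, p$scale,
                                   lower.tail = FALSE, log.p = TRUE),
    normal       = stats::pnorm(y, p$mean, p$sd,
                                lower.tail = FALSE, log.p = TRUE),
    lognormal    = stats::plnorm(y, p$meanlog, p$sdlog,
                                 lower.tail = FALSE, log.p = TRUE),
    loglogistic  = {
      # S(y) = 1/(1 + (y/s)^k)
      ifelse(y <= 0, 0,
             -log1pexp(p$shape * (log(pmax(y, .Machine$double.xmin)) -
                                    log(p$scale))))
    },
    binomial     = ,
    betabinomial = count_log_cdf(spec, y, lower_tail = FALSE)
  )
}

check_support <- function(spec, y) {
  bad <- switch(spec$support,
    "continuous-positive" = y <= 0,
    "continuous-real"     = !is.finite(y),
    "integer-count"       = y < 0 | y != round(y) |
      y > rep_len(spec$params$size, length(y))
  )
  if (any(bad)) {
    stop("outcome value ", format(y[which(bad)[1]]),
         " is outside the support of the ", spec$family, " family",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Draw from a parametric family
#'
#' Simulation companion to [family_spec()]; used by the synthetic-data
#' generators and by the Monte-Carlo distribution checks in the test suite.
#'
#' @param spec A [family_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
family_rng <- function(spec, n) {
  p <- spec$params
  switch(spec$family,
    exponential  = stats::rexp(n, p$rate),
    weibull      = stats::rweibull(n, p$shape, p$scale),
    normal       = stats::rnorm(n, p$mean, p$sd),
    lognormal    = stats::rlnorm(n, p$meanlog, p$sdlog),
    loglogistic  = {
      u <- stats::runif(n)
      p$scale * (u / (1 - u))^(1 / p$shape)
    },
    binomial     = stats::rbinom(n, p$size, p$prob),
    betabinomial = stats::rbinom(n, p$size,
                                 stats::rbeta(n, p$shape1, p$shape2))
  )
}

# numerically careful log(1 + e^x)
log1pexp <- function(x) {
  out <- numeric(length(x))
  lo <- x <= -37
  hi <- x > 33.3
  mid <- !lo & !hi
  out[lo] <- exp(x[lo])
  out[mid] <- log1p(exp(x[mid]))
  out[hi] <- x[hi]
  out
}

PROB_EPS <- 1e-12

#' Link functions
#'
#' Forward links map a probability in (0, 1) to the real line; inverse links
#' map back. Inverse-link output is clipped to
#' \eqn{[10^{-12}, 1 - 10^{-12}]} so that a Bernoulli log probability built
#' from it can never be \eqn{-\infty}.
#'
#' @param link One of `"logit"`, `"probit"`, `"cloglog"`, `"identity"`.
#' @param x Real value(s) (inverse direction).
#' @param p Probability value(s) (forward direction).
#' @return `inverse_link()`: probabilities in (0, 1); `link_fun()`: reals.
#' @examples
#' inverse_link("cloglog", 0)  # 1 - exp(-1)
#' @export
inverse_link <- function(link, x) {
  link <- match.arg(link, c("logit", "probit", "cloglog", "identity"))
  p <- switch(link,
    logit    = stats::plogis(x),
    probit   = stats::pnorm(x),
    cloglog  = -expm1(-exp(x)),
    identity = x
  )
  pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)
}

#' @rdname inverse_link
#' @export
link_fun <- function(link, p) {
  link <- match.arg(link, c("logit", "probit", "cloglog", "identity"))
  switch(link,
    logit    = stats::qlogis(p),
    probit   = stats::qnorm(p),
    cloglog  = log(-log1p(-p)),
    identity = p
  )
}
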