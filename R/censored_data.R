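#' Censored datasets and their observation blocks
#'
#' A `censored_data` object holds outcome records that are observed exactly
#' or known only up to a cutoff, and partitions them into the three blocks
#' the likelihood treats differently:
#' \describe{
#'   \item{O}{observed outcomes, contributing log density terms;}
#'   \item{C}{one-sided (left- or right-) censored outcomes, contributing
#'     log distribution-function or log survivor terms;}
#'   \item{I}{interval-censored outcomes on a semi-closed interval
#'     \eqn{(l, u]}, contributing \eqn{\log\{F(u) - F(l)\}}.}
#' }
#'
#' @param value Numeric outcome; must be present for `status == "observed"`
#'   and `NA` otherwise.
#' @param status Character vector with entries `"observed"`, `"left"`,
#'   `"right"` or `"interval"`.
#' @param lower Lower cutoff; required for `"right"` and `"interval"`.
#' @param upper Upper cutoff; required for `"left"` and `"interval"`.
#' @param covariates Optional data frame of per-record covariates.
#' @return A `censored_data` object: a list with the validated record table
#'   (`records`), block index vectors `O`, `C`, `I`, and `n`.
#' @examples
#' d <- censored_data(
#'   value  = c(1.0, NA, NA),
#'   status = c("observed", "right", "interval"),
#'   lower  = c(NA, 2.0, 0.5),
#'   upper  = c(NA, NA, 1.5)
#' )
#' d$O; d$C; d$I
#' @export
censored_data <- function(value, status,
                          lower = rep(NA_real_, length(status)),
                          upper = rep(NA_real_, length(status)),
                          covariates = NULL) {
  n <- length(status)
  status <- as.character(status)
  value <- rep_len(as.numeric(value), n)
  lower <- rep_len(as.numeric(lower), n)
  upper <- rep_len(as.numeric(upper), n)
  ok_status <- status %in% c("observed", "left", "right", "interval")
  if (any(!ok_status)) {
    stop("record ", which(!ok_status)[1], ": unknown censoring status '",
         status[which(!ok_status)[1]], "'", call. = FALSE)
  }
  fail <- function(i, msg) {
    stop("record ", i, ": ", msg, call. = FALSE)
  }
  for (i in seq_len(n)) {
    switch(status[i],
      observed = {
        if (is.na(value[i])) fail(i, "observed record needs a value")
        if (!is.na(lower[i]) || !is.na(upper[i]))
          fail(i, "observed record must not carry cutoffs")
      },
      left = {
        if (is.na(upper[i])) fail(i, "left-censored record needs an upper cutoff")
        if (!is.na(value[i])) fail(i, "censored record must not carry a value")
      },
      right = {
        if (is.na(lower[i])) fail(i, "right-censored record needs a lower cutoff")
        if (!is.na(value[i])) fail(i, "censored record must not carry a value")
      },
      interval = {
        if (is.na(lower[i]) || is.na(upper[i]))
          fail(i, "interval-censored record needs both cutoffs")
        if (lower[i] >= upper[i])
          fail(i, "interval-censored record needs lower < upper strictly")
        if (!is.na(value[i])) fail(i, "censored record must not carry a value")
      }
    )
  }
  records <- data.frame(value = value, status = status,
                        lower = lower, upper = upper)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      stop("covariates must have one row per record", call. = FALSE)
    records <- cbind(records, covariates)
  }
  blocks <- partition_blocks(status)
  # plain vectors kept alongside the record table: the likelihood hot path
  # indexes these rather than subsetting the data frame
  structure(c(list(records = records, n = n, value = value, status = status,
                   lower = lower, upper = upper), blocks),
            class = "censored_data")
}

#' Partition censoring statuses into the O / C / I blocks
#'
#' @param status Character vector of statuses (or a `censored_data` object).
#' @return List with integer index vectors `O` (observed), `C` (left/right
#'   censored) and `I` (interval censored); the three are disjoint and
#'   exhaustive, preserving original record order within each block.
#' @export
partition_blocks <- function(status) {
  if (inherits(status, "censored_data")) status <- status$records$status
  list(
    O = which(status == "observed"),
    C = which(status %in% c("left", "right")),
    I = which(status == "interval")
  )
}

#' @export
print.censored_data <- function(x, ...) {
  cat("<censored_data> ", x$n, " records: |O| = ", length(x$O),
      ", |C| = ", length(x$C), " (left/right), |I| = ", length(x$I),
      " (interval)\n", sep = "")
  invisible(x)
}

#' Attach the Bernoulli censoring indicators
#'
#' Augments a censored dataset with the fixed indicator variables that turn
#' censored contributions into Bernoulli likelihood blocks: `Z1 = 1` for a
#' left-censored record and `Z1 = 0` for a right-censored one (block C), and
#' `Z2 = 1` for every interval-censored record (block I). The indicators are
#' deterministic functions of the censoring pattern — they are data, not
#' latent variables to be sampled — and the Bernoulli success probabilities
#' come from the outcome family's distribution function at the cutoffs.
#'
#' @param data A [censored_data()] object.
#' @return An `augmented_data` object: the input plus integer vectors `Z1`
#'   (aligned with block `C`) and `Z2` (aligned with block `I`).
#' @export
bernoulli_augment <- function(data) {
  stopifnot(inherits(data, "censored_data"))
  Z1 <- as.integer(data$records$status[data$C] == "left")
  Z2 <- rep(1L, length(data$I))
  structure(list(base = data, Z1 = Z1, Z2 = Z2), class = "augmented_data")
}

#' @export
print.augmented_data <- function(x, ...) {
  cat("<augmented_data> base of ", x$base$n, " records; Z1 (C block): ",
      paste(x$Z1, collapse = " "), "; Z2 (I block): length ",
      length(x$Z2), "\n", sep = "")
  invisible(x)
}
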