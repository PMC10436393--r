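#' Kaplan-Meier estimator of disease-free survival
#'
#' Product-limit estimate via [survival::survfit()].
#'
#' @param time positive event/censoring times.
#' @param event 1 = event (relapse), 0 = censored.
#' @return data.frame with `time`, `n_risk`, `n_event`, `surv` (the
#'   right-continuous step values at the observed times).
#' @examples
#' km_estimator(c(1, 2), c(1, 1))$surv  # 0.5, 0
#' @export
km_estimator <- function(time, event) {
  if (!length(time)) stop("empty survival input")
  stopifnot(length(time) == length(event), all(time > 0), all(event %in% 0:1))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv)
}

# Vectorized two-group logrank over many candidate groupings.
#
# time, event: length-n survival data. on: n x T logical/0-1 matrix, one
# column per candidate ON/OFF split. Returns per column the observed and
# expected ON-group event counts, the O-E/V chi-square (1 df), its p-value
# and the Pike (O/E-ratio) hazard-ratio estimate for ON vs OFF.
.logrank_core <- function(time, event, on) {
  n <- length(time)
  if (!is.matrix(on)) on <- matrix(on, nrow = n)
  storage.mode(on) <- "double"
  o <- order(time)
  ts <- time[o]; es <- event[o]; G <- on[o, , drop = FALSE]

  # at-risk counts: samples with time >= t_j, computed at first index of
  # each distinct time value
  first <- which(!duplicated(ts))
  n_at <- n - first + 1L
  Rc <- apply(G[n:1, , drop = FALSE], 2L, cumsum)[n:1, , drop = FALSE]
  n1_at <- Rc[first, , drop = FALSE]

  grp <- cumsum(!duplicated(ts))          # distinct-time index per sample
  d <- rowsum(es, grp)                    # events per distinct time
  d1 <- rowsum(G * es, grp)               # ON events per distinct time
  ev <- which(d > 0)
  d <- d[ev]; d1 <- d1[ev, , drop = FALSE]
  n_at <- n_at[ev]; n1_at <- n1_at[ev, , drop = FALSE]

  p1 <- n1_at / n_at
  U <- colSums(d1 - d * p1)
  vterm <- d * p1 * (1 - p1) * (n_at - d) / pmax(n_at - 1, 1)
  vterm[n_at <= 1, ] <- 0
  V <- colSums(vterm)
  chisq <- ifelse(V > 0, U^2 / V, NA_real_)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  O1 <- colSums(d1); E1 <- colSums(d * p1)
  O0 <- sum(d) - O1; E0 <- sum(d) - E1
  hr <- (O1 / E1) / (O0 / E0)
  list(statistic = chisq, p = p, U = U, V = V,
       obs_on = O1, exp_on = E1, hr_pike = hr)
}

#' Two-group logrank test
#'
#' Standard logrank chi-square (1 df) between two survival groups, computed
#' from the observed-minus-expected event counts with the hypergeometric
#' variance. Also reports the Pike estimator of the hazard ratio,
#' `(O1/E1) / (O0/E0)`, for group `TRUE` vs group `FALSE`.
#'
#' @param time,event survival data (see [km_estimator()]).
#' @param group logical (or two-level) group indicator.
#' @return list with `statistic`, `p`, `obs_on`, `exp_on`, `hr_pike`.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (!is.logical(group)) {
    lv <- unique(group)
    if (length(lv) != 2) stop("`group` must have exactly two levels")
    group <- group == lv[2]
  }
  if (!any(group) || all(group)) stop("both groups must be non-empty")
  if (sum(event) < 1) stop("need at least one event")
  res <- .logrank_core(time, event, matrix(as.numeric(group), ncol = 1))
  lapply(res, function(x) x[[1]])
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit via [survival::coxph()] with Efron handling of
#' tied event times; returns per-covariate hazard ratios and Wald p-values.
#'
#' @param time,event survival data.
#' @param covariates data.frame (or named list) of covariates; constant
#'   columns are dropped with a warning.
#' @return data.frame with `term`, `coef`, `hr`, `se`, `p`; attribute
#'   `converged`.
#' @export
cox_fit <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(time))
  if (sum(event, na.rm = TRUE) < 1) stop("need at least one event")
  keep <- vapply(covariates, function(x) length(unique(x[!is.na(x)])) > 1,
                 logical(1))
  if (!all(keep)) {
    warning("dropping constant covariate(s): ",
            paste(names(covariates)[!keep], collapse = ", "))
    covariates <- covariates[, keep, drop = FALSE]
  }
  if (!ncol(covariates)) stop("no usable (non-constant) covariates")
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = dat, ties = "efron"),
    error = function(e) NULL, warning = function(w) {
      withCallingHandlers(
        suppressWarnings(survival::coxph(fml, data = dat, ties = "efron")),
        warning = function(w) invokeRestart("muffleWarning"))
    })
  if (is.null(fit)) {
    out <- data.frame(term = names(covariates), coef = NA_real_,
                      hr = NA_real_, se = NA_real_, p = NA_real_)
    attr(out, "converged") <- FALSE
    return(out)
  }
  s <- summary(fit)$coefficients
  out <- data.frame(term = rownames(s), coef = s[, "coef"],
                    hr = exp(s[, "coef"]), se = s[, "se(coef)"],
                    p = s[, "Pr(>|z|)"], row.names = NULL,
                    stringsAsFactors = FALSE)
  out$term <- gsub("`", "", out$term)
  attr(out, "converged") <- TRUE
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (wraps [stats::p.adjust()] after range
#' validation).
#'
#' @param p numeric p-values in `[0, 1]` (`NA` allowed, propagated).
#' @return Adjusted p-values, same length/order as the input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
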