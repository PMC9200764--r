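# Negative log Cox partial likelihood and its gradient w.r.t. the risks.
# Breslow tie handling shares the full risk set across tied events (the
# untied form reduces to it); Efron's correction is available by `ties`.
cox_pl <- function(risks, times, events, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  n <- length(risks)
  if (n == 0L) stop_validation("cox_nll: empty input")
  if (length(times) != n || length(events) != n) {
    stop_validation("cox_nll: risks, times and events must have equal length")
  }
  if (!all(events %in% c(0, 1))) stop_validation("cox_nll: events must be 0/1")
  if (!any(events == 1)) return(list(loss = 0, grad = numeric(n)))

  mx <- max(risks)                  # log-sum-exp stabilisation
  er <- exp(risks - mx)

  if (ties == "breslow") {
    # risk-set sums S(t_k) = sum_{t_j >= t_k} e^{r_j} for every subject
    o <- order(times, decreasing = TRUE)
    cse <- cumsum(er[o])
    runs <- rle(times[o])
    ends <- cumsum(runs$lengths)
    rs_sorted <- cse[rep(ends, runs$lengths)]
    rs <- numeric(n); rs[o] <- rs_sorted

    ev <- events == 1
    loss <- -sum(risks[ev] - mx - log(rs[ev]))

    # grad_k = -delta_k + e^{r_k} * sum_{events m with t_m <= t_k} 1 / S(t_m)
    a <- order(times)
    contrib <- (events / rs)[a]
    cums <- cumsum(contrib)
    runs2 <- rle(times[a])
    ends2 <- cumsum(runs2$lengths)
    Wk <- numeric(n); Wk[a] <- cums[rep(ends2, runs2$lengths)]
    grad <- -events + er * Wk
    return(list(loss = loss, grad = grad))
  }

  # Efron
  loss <- 0
  grad <- -as.numeric(events)
  ev_times <- sort(unique(times[events == 1]))
  for (t in ev_times) {
    at_risk <- times >= t
    dset <- which(events == 1 & times == t)
    d <- length(dset)
    S <- sum(er[at_risk])
    Sd <- sum(er[dset])
    l <- seq_len(d) - 1
    denom <- S - (l / d) * Sd
    loss <- loss - sum(risks[dset] - mx) + sum(log(denom))
    inv <- 1 / denom
    grad[at_risk] <- grad[at_risk] + er[at_risk] * sum(inv)
    grad[dset] <- grad[dset] - er[dset] * sum((l / d) * inv)
  }
  list(loss = loss, grad = grad)
}

#' Cox negative log partial likelihood
#'
#' The training loss for weakly supervised survival learning:
#' `l = -sum_{m: event} [ r_m - log sum_{j in R(t_m)} exp(r_j) ]` with risk
#' set `R(t_m) = { j : t_j >= t_m }`, computed with max-subtraction for
#' numerical stability. Tied event times use the Breslow approximation by
#' default (`ties = "efron"` switches to Efron's correction). With no
#' observed events the loss is 0 (an empty sum).
#'
#' @param risks numeric risk scores.
#' @param times survival / follow-up times in months.
#' @param events 0/1 event indicators (1 = death observed).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return scalar loss.
#' @export
cox_nll <- function(risks, times, events, ties = "breslow") {
  cox_pl(risks, times, events, ties)$loss
}

#' @rdname cox_nll
#' @return `cox_nll_grad`: gradient of the loss w.r.t. `risks`.
#' @export
cox_nll_grad <- function(risks, times, events, ties = "breslow") {
  cox_pl(risks, times, events, ties)$grad
}
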