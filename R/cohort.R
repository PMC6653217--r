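#' NMF clustering of a patient cohort
#'
#' Frobenius non-negative matrix factorization `X ~ W H` by multiplicative
#' updates (whose objective is non-increasing every iteration), run from
#' `nRestarts` random initializations; the restart with the smallest
#' squared reconstruction error wins. Patients are assigned to the argmax
#' component of their coefficient column.
#'
#' @param x non-negative genes x patients matrix (log2(x+1)-transform
#'   count-like data upstream; see `logTransform`).
#' @param k number of components (default 2).
#' @param nRestarts random restarts (default 30).
#' @param maxIter iterations per restart (default 200).
#' @param tol stop a restart early when the relative objective decrease
#'   falls below this (default 1e-6).
#' @param seed RNG seed; the result is deterministic given the seed.
#' @param logTransform apply `log2(x + 1)` before factorizing (default
#'   FALSE: the caller transforms).
#' @return an [NmfResult-class].
#' @export
nmfCluster <- function(x, k = 2L, nRestarts = 30L, maxIter = 200L,
                       tol = 1e-6, seed = 1L, logTransform = FALSE) {
  x <- as.matrix(x)
  if (logTransform) x <- log2(x + 1)
  if (any(x < 0)) stop("matrix must be non-negative for NMF")
  stopIfNot(k >= 2, "k must be >= 2")
  set.seed(seed)
  eps <- .Machine$double.eps
  best <- NULL
  for (r in seq_len(nRestarts)) {
    W <- matrix(runif(nrow(x) * k, 0.1, 1), nrow(x), k)
    H <- matrix(runif(k * ncol(x), 0.1, 1), k, ncol(x))
    obj <- sum((x - W %*% H)^2)
    trace <- obj
    for (it in seq_len(maxIter)) {
      H <- H * (crossprod(W, x) / (crossprod(W, W %*% H) + eps))
      W <- W * (x %*% t(H)) / (W %*% tcrossprod(H) + eps)
      newObj <- sum((x - W %*% H)^2)
      trace <- c(trace, newObj)
      if ((obj - newObj) < tol * obj) { obj <- newObj; break }
      obj <- newObj
    }
    if (is.null(best) || obj < best$obj)
      best <- list(W = W, H = H, obj = obj, trace = trace)
  }
  cl <- apply(best$H, 2, which.max)
  new("NmfResult", basis = best$W, coef = best$H,
      cluster = as.integer(cl), objective = best$trace,
      seed = as.integer(seed))
}

#' Pearson chi-square association of clusters with labels
#'
#' 2x2 contingency test without continuity correction (1 df); the
#' correction can be enabled to match software that applies it.
#'
#' @param clusters,labels equal-length vectors of group assignments.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list with `statistic`, `p`, `table`.
#' @export
contingencyChisq <- function(clusters, labels, correct = FALSE) {
  tab <- table(clusters, labels)
  if (nrow(tab) < 2 || ncol(tab) < 2 ||
      any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has a zero margin")
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value),
       table = tab)
}

#' Mean-split expression grouping
#'
#' Patients with expression strictly greater than the arithmetic mean form
#' the high group; everyone else (including values equal to the mean) is
#' low. A median split is available for robustness.
#'
#' @param values numeric expression values per patient (>= 2).
#' @param center "mean" (default) or "median".
#' @return character vector "high"/"low".
#' @export
splitByMean <- function(values, center = c("mean", "median")) {
  stopIfNot(length(values) >= 2, "need at least 2 patients to split")
  center <- match.arg(center)
  c0 <- if (center == "mean") mean(values) else stats::median(values)
  ifelse(values > c0, "high", "low")
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function from follow-up times
#' and event indicators (computed with the survival package).
#'
#' @param time follow-up times (>= 0).
#' @param event event indicators (1 = event, 0 = censored).
#' @return data.frame `time`, `n_risk`, `n_event`, `surv` (stepwise
#'   survival probability at each observed time).
#' @export
kmCurve <- function(time, event) {
  if (any(time < 0)) stop("negative follow-up time")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Evaluate a KM curve at given times
#' @param curve data.frame from [kmCurve()].
#' @param at times to evaluate at.
#' @return survival probabilities `S(t)` (right-continuous step function,
#'   `S(0) = 1`).
#' @export
kmAt <- function(curve, at) {
  vapply(at, function(t) {
    i <- which(curve$time <= t)
    if (!length(i)) 1 else curve$surv[max(i)]
  }, numeric(1))
}

#' Log-rank test between two survival groups
#'
#' Standard log-rank chi-square (1 df): observed minus
#' hypergeometric-expected events in group 1 summed over event times,
#' squared and divided by the summed variance.
#'
#' @param timeHigh,eventHigh follow-up and event indicator, high group.
#' @param timeLow,eventLow follow-up and event indicator, low group.
#' @return list with `statistic`, `p`.
#' @export
logrankTest <- function(timeHigh, eventHigh, timeLow, eventLow) {
  stopIfNot(length(timeHigh) > 0 && length(timeLow) > 0,
            "both groups must be non-empty")
  if (sum(eventHigh) + sum(eventLow) == 0) {
    warning("no events in either group; log-rank undefined, p = 1")
    return(list(statistic = 0, p = 1))
  }
  time <- c(timeHigh, timeLow)
  event <- c(eventHigh, eventLow)
  grp <- rep(c("high", "low"), c(length(timeHigh), length(timeLow)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, rho = 0)
  list(statistic = unname(sd$chisq),
       p = pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE))
}
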