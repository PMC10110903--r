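# Censored survival statistics, implemented from scratch: Kaplan-Meier
# product-limit curves, the log-rank test, the binary-covariate Cox model
# (Breslow tie handling) with Wald 95% CI, Harrell's concordance index, and
# Cramer's phi for 2x2 agreement. Two-sided alpha = 0.05 conventions
# throughout; the survival package is used only as an independent
# cross-check in the test suite.

.check_records <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1,
            all(time > 0), all(event %in% c(0, 1)))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator over the distinct event times: S(t) is the
#' running product of (1 - d_j / n_j) with d_j events among n_j at risk.
#' S(0) = 1 and the curve is a right-continuous step function.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators (0 = censored).
#' @return data.frame with columns time, n_risk, n_event, surv, one row per
#'   distinct event time.
#' @examples
#' kmCurve(c(1, 2, 3), c(1, 1, 0))$surv  # 2/3, 1/3
#' @export
kmCurve <- function(time, event) {
  .check_records(time, event)
  et <- sort(unique(time[event == 1]))
  if (!length(et))
    return(data.frame(time = numeric(), n_risk = numeric(),
                      n_event = numeric(), surv = numeric()))
  n_risk <- vapply(et, function(t) sum(time >= t), 0)
  n_event <- vapply(et, function(t) sum(time == t & event == 1), 0)
  data.frame(time = et, n_risk = n_risk, n_event = n_event,
             surv = cumprod(1 - n_event / n_risk))
}

#' Evaluate a Kaplan-Meier curve at given times
#' @param curve result of [kmCurve()].
#' @param at times to evaluate at.
#' @return survival probabilities (right-continuous steps, S(0) = 1).
#' @export
kmSurvAt <- function(curve, at) {
  vapply(at, function(t) {
    i <- which(curve$time <= t)
    if (!length(i)) 1 else curve$surv[max(i)]
  }, 0)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' accumulated over the pooled distinct event times; the p-value comes from
#' a chi-square with one degree of freedom. With zero events overall the
#' statistic is 0 and p = 1.
#'
#' @param timeA,eventA records of group A.
#' @param timeB,eventB records of group B.
#' @return list with chi_square, p, observed/expected events in group A.
#' @export
logrankTest <- function(timeA, eventA, timeB, eventB) {
  .check_records(timeA, eventA)
  .check_records(timeB, eventB)
  time <- c(timeA, timeB)
  event <- c(eventA, eventB)
  grp <- rep(c(1, 0), c(length(timeA), length(timeB)))
  et <- sort(unique(time[event == 1]))
  if (!length(et))
    return(list(chi_square = 0, p = 1, observed = 0, expected = 0))
  O <- E <- V <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- if (V > 0) (O - E)^2 / V else 0
  list(chi_square = chi, p = pchisq(chi, df = 1, lower.tail = FALSE),
       observed = O, expected = E)
}

# Breslow log partial likelihood, score and information for a single
# binary covariate; events are summed individually over the full risk set.
.cox_breslow <- function(beta, time, event, x) {
  idx <- which(event == 1)
  ll <- sc <- info <- 0
  for (i in idx) {
    at_risk <- time >= time[i]
    s0 <- sum(exp(beta * x[at_risk]))
    s1 <- sum(x[at_risk] * exp(beta * x[at_risk]))
    ll <- ll + beta * x[i] - log(s0)
    sc <- sc + x[i] - s1 / s0
    info <- info + s1 / s0 - (s1 / s0)^2  # x binary: s2 = s1
  }
  list(loglik = ll, score = sc, info = info)
}

#' Binary-covariate Cox hazard ratio
#'
#' Newton-Raphson maximization of the Breslow partial likelihood for a
#' single 0/1 group covariate; the hazard ratio is exp(beta) with a Wald
#' 95% CI exp(beta +/- 1.96 SE). Convergence requires |score| < 1e-10. A
#' monotone likelihood (all events effectively separating the groups) is
#' flagged and reported with an unbounded CI.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @param group 0/1 (or two-level factor) group labels.
#' @return list with hr, ci_low, ci_high, beta, se, p (Wald), flagged.
#' @export
coxHRBinary <- function(time, event, group) {
  .check_records(time, event)
  x <- if (is.factor(group)) as.numeric(group) - 1 else as.numeric(group)
  stopifnot(all(x %in% c(0, 1)))
  if (sum(event) < 1) stop("at least one event required")
  beta <- 0
  flagged <- FALSE
  for (iter in 1:100) {
    d <- .cox_breslow(beta, time, event, x)
    if (d$info <= 1e-12 || abs(beta) > 20) { flagged <- TRUE; break }
    if (abs(d$score) < 1e-10) break
    step <- d$score / d$info
    beta <- beta + sign(step) * min(abs(step), 2)  # damped Newton
  }
  d <- .cox_breslow(beta, time, event, x)
  if (abs(d$score) >= 1e-8 || abs(beta) > 20) flagged <- TRUE
  se <- if (d$info > 0) 1 / sqrt(d$info) else Inf
  if (flagged) {
    warning("monotone partial likelihood: hazard ratio unbounded")
    return(list(hr = exp(beta), ci_low = 0, ci_high = Inf, beta = beta,
                se = Inf, p = NA_real_, flagged = TRUE))
  }
  z <- beta / se
  list(hr = exp(beta),
       ci_low = exp(beta - 1.96 * se),
       ci_high = exp(beta + 1.96 * se),
       beta = beta, se = se,
       p = 2 * pnorm(-abs(z)),
       flagged = FALSE)
}

#' Harrell's concordance index
#'
#' Over all usable pairs -- those whose strictly earlier follow-up time
#' ends in an event -- a pair is concordant (1) when the earlier-event
#' patient has the higher risk score, tied scores count 0.5, discordant
#' pairs 0; c is the mean. c = 1 is perfect concordance of risk with
#' outcome, c = 0.5 is chance. Pairs tied on time are unusable (Harrell's
#' original convention).
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @param score continuous risk score (higher = predicted worse survival).
#' @return concordance index in [0, 1].
#' @export
harrellsC <- function(time, event, score) {
  .check_records(time, event)
  stopifnot(length(score) == length(time))
  num <- den <- 0
  for (i in which(event == 1)) {
    later <- time > time[i]
    n_later <- sum(later)
    if (!n_later) next
    den <- den + n_later
    num <- num + sum(score[i] > score[later]) +
      0.5 * sum(score[i] == score[later])
  }
  if (den == 0) stop("c undefined: no usable pairs")
  num / den
}

#' Bootstrap standard error of Harrell's c
#'
#' Nonparametric bootstrap over patients, seeded.
#'
#' @param time,event,score as in [harrellsC()].
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @return list with c, se, replicates used (resamples without usable
#'   pairs are dropped).
#' @export
harrellsCBoot <- function(time, event, score, B = 200, seed) {
  if (missing(seed)) stop("seed required for reproducibility")
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  n <- length(time)
  reps <- numeric(0)
  for (b in seq_len(B)) {
    ix <- sample.int(n, replace = TRUE)
    ci <- tryCatch(harrellsC(time[ix], event[ix], score[ix]),
                   error = function(e) NA_real_)
    if (!is.na(ci)) reps <- c(reps, ci)
  }
  list(c = harrellsC(time, event, score), se = sd(reps), B_used = length(reps))
}

#' Cramer's phi for a 2x2 table
#'
#' phi = (n11 n22 - n12 n21) / sqrt(r1 r2 c1 c2); interpretable like a
#' correlation coefficient, with 1 indicating perfect agreement. The
#' p-value comes from chi-square = n phi^2 on one degree of freedom.
#'
#' @param table 2x2 matrix of nonnegative counts.
#' @return list with phi, chi_square, p, n.
#' @examples
#' cramersPhi(matrix(c(10, 0, 0, 10), 2))$phi  # 1
#' @export
cramersPhi <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2), all(table >= 0))
  n <- sum(table)
  if (n < 1) stop("empty table")
  r <- rowSums(table); cl <- colSums(table)
  if (any(r == 0) || any(cl == 0))
    stop("phi undefined: zero margin")
  phi <- (table[1, 1] * table[2, 2] - table[1, 2] * table[2, 1]) /
    sqrt(prod(r) * prod(cl))
  chi <- n * phi^2
  list(phi = phi, chi_square = chi,
       p = pchisq(chi, df = 1, lower.tail = FALSE), n = n)
}

#' @importFrom stats pnorm
NULL
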