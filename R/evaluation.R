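#' First-encounter event times for a state
#'
#' The survival event is the first encounter of state `s` in a subject's
#' labelled sequence; later occurrences are ignored. Subjects who never
#' show `s` are censored at their last labelled bin.
#'
#' @param labels data frame with columns `subject`, `bin`, `state`
#'   (0-based bins on the common grid).
#' @param s target state in 1-4.
#' @return Data frame with one row per subject: `subject`, `time` (bin),
#'   `event` (logical).
#' @export
first_event_times <- function(labels, s) {
  labels <- as.data.frame(labels)
  if (!nrow(labels))
    return(data.frame(subject = character(0), time = numeric(0),
                      event = logical(0)))
  sp <- split(labels[c("bin", "state")], labels$subject)
  out <- lapply(names(sp), function(id) {
    d <- sp[[id]]
    hit <- d$bin[d$state == s]
    if (length(hit)) data.frame(subject = id, time = min(hit), event = TRUE)
    else data.frame(subject = id, time = max(d$bin), event = FALSE)
  })
  do.call(rbind, out)
}

#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator: at each distinct event time `t`,
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` with `d_i` events and `n_i`
#' subjects at risk. Subjects censored at an event time are counted at
#' risk through that time. `S` is 1 before the first event.
#'
#' @param pairs data frame with columns `time` and `event` (logical), as
#'   from [first_event_times()].
#' @return An object of class `"survival_curve"`: `time` (distinct event
#'   times), `surv`, `n_risk`, `n_event`, `n` (subjects).
#' @export
km_estimate <- function(pairs) {
  if (is.null(pairs) || !nrow(pairs)) stop("no subjects")
  tt <- sort(unique(pairs$time[pairs$event]))
  if (!length(tt))
    return(structure(list(time = numeric(0), surv = numeric(0),
                          n_risk = integer(0), n_event = integer(0),
                          n = nrow(pairs)), class = "survival_curve"))
  n_risk <- vapply(tt, function(t) sum(pairs$time >= t), numeric(1))
  n_event <- vapply(tt, function(t) sum(pairs$event & pairs$time == t),
                    numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(time = tt, surv = surv, n_risk = n_risk,
                 n_event = n_event, n = nrow(pairs)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve> %d subjects, %d event times, S(last) = %s\n",
              x$n, length(x$time),
              if (length(x$surv)) sprintf("%.3f", x$surv[length(x$surv)])
              else "1"))
  invisible(x)
}

#' Evaluate a survival curve on a set of times
#'
#' Step-function evaluation: the value at `t` is the product-limit estimate
#' at the last event time `<= t`, and 1 before the first event.
#'
#' @param curve a [km_estimate()] result.
#' @param times numeric vector.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, times) {
  if (!length(curve$time)) return(rep(1, length(times)))
  c(1, curve$surv)[findInterval(times, curve$time) + 1L]
}

#' Bootstrap equivalence margin for a Kaplan-Meier curve
#'
#' The margin `delta(t) = width_factor * sigma_hat(S(t))` with the
#' pointwise standard deviation estimated from `B` bootstrap resamples of
#' the subjects (default 1000 replicates, width factor 2).
#'
#' @param pairs data frame of `(time, event)` pairs.
#' @param times evaluation times (bin grid).
#' @param B number of bootstrap replicates (>= 2).
#' @param width_factor multiplier on the bootstrap standard deviation.
#' @param seed integer seed.
#' @return Numeric vector `delta(t)` along `times`.
#' @export
km_margin <- function(pairs, times, B = 1000L, width_factor = 2,
                      seed = 1L) {
  stopifnot(B >= 2)
  set.seed(seed)
  n <- nrow(pairs)
  S <- matrix(NA_real_, B, length(times))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    S[b, ] <- km_survival_at(km_estimate(pairs[idx, , drop = FALSE]), times)
  }
  width_factor * apply(S, 2, sd)
}

#' Probability-of-agreement curve between two survival estimates
#'
#' `phi(t) = p(|S(t) - Shat(t)| <= delta(t))`, estimated by a paired
#' bootstrap: the two cohorts are resampled jointly `B` times (the same
#' subject indices for both when they are paired, i.e. of equal size) and
#' `phi(t)` is the fraction of replicates whose curves differ by at most
#' `delta(t)`.
#'
#' @param truth_pairs,pred_pairs `(time, event)` data frames on the common
#'   grid; equal row counts are resampled jointly, otherwise the cohorts
#'   are resampled independently.
#' @param delta margin `delta(t)` along `times`, e.g. from [km_margin()].
#' @param times evaluation times.
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @return Numeric vector `phi(t)` in `[0, 1]` along `times`.
#' @export
poa_curve <- function(truth_pairs, pred_pairs, delta, times, B = 1000L,
                      seed = 1L) {
  set.seed(seed)
  n1 <- nrow(truth_pairs); n2 <- nrow(pred_pairs)
  paired <- n1 == n2
  agree <- matrix(NA, B, length(times))
  for (b in seq_len(B)) {
    i1 <- sample.int(n1, n1, replace = TRUE)
    i2 <- if (paired) i1 else sample.int(n2, n2, replace = TRUE)
    S1 <- km_survival_at(km_estimate(truth_pairs[i1, , drop = FALSE]),
                         times)
    S2 <- km_survival_at(km_estimate(pred_pairs[i2, , drop = FALSE]),
                         times)
    agree[b, ] <- abs(S1 - S2) <= delta
  }
  colMeans(agree)
}

#' Normalized area under the probability-of-agreement curve
#'
#' `Phi = 1/(T - t0) * int_{t0}^{T} phi(t) dt` by the trapezoid rule;
#' `Phi = 1` indicates perfect agreement over the window.
#'
#' @param phi agreement curve along `times`.
#' @param times evaluation times spanning `[t0, T]`.
#' @return Scalar in `[0, 1]`.
#' @export
poa_score <- function(phi, times) {
  if (length(times) < 2 || max(times) <= min(times))
    stop("need a non-degenerate time window")
  trapezoid(times, phi) / (max(times) - min(times))
}

#' Probability of agreement between truth and prediction cohorts
#'
#' Convenience wrapper: estimates the margin `delta(t)` from the truth
#' cohort (`width_factor` times the bootstrap standard deviation of its
#' Kaplan-Meier curve), the agreement curve `phi(t)` by paired bootstrap,
#' and the normalized area `Phi`.
#'
#' @inheritParams poa_curve
#' @param width_factor margin width in bootstrap standard deviations.
#' @return An object of class `"agreement_result"`: `phi`, `delta`,
#'   `times`, `Phi`, `B`.
#' @export
agreement <- function(truth_pairs, pred_pairs, times, B = 1000L,
                      width_factor = 2, seed = 1L) {
  delta <- km_margin(truth_pairs, times, B = B,
                     width_factor = width_factor, seed = seed)
  phi <- poa_curve(truth_pairs, pred_pairs, delta, times, B = B,
                   seed = seed + 1L)
  structure(list(phi = phi, delta = delta, times = times,
                 Phi = poa_score(phi, times), B = B),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> Phi = %.3f over %d bins (B = %d)\n",
              x$Phi, length(x$times), x$B))
  invisible(x)
}
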