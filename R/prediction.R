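# log of the per-state kernel normaliser: logC(m) = -log sum_s exp(-theta (s-m)^2)
log_kernel_const <- function(m, theta) {
  a <- vapply(1:4, function(s) -theta * (s - m)^2, numeric(length(m)))
  a <- matrix(a, ncol = 4)
  mx <- apply(a, 1, max)
  -(mx + log(rowSums(exp(a - mx))))
}

log_sum_exp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

#' Probabilities of the next screening state
#'
#' Estimates `p(x_target = s | x)` for an individual's sparse history `x`
#' by marginalising the observation kernel over the empirical distribution
#' of fitted latent profiles: each training profile contributes the kernel
#' mass at the target bin times the kernel mass of every prior observation.
#' For shifted variants the shift-adjusted latent matrix is used. The
#' accumulation runs in the log domain with max subtraction: with
#' thousands of training rows and long histories the literal product
#' underflows.
#'
#' @param model a fitted [fit_factor_model()].
#' @param history data frame with columns `bin` (0-based) and `state`, the
#'   individual's prior observations.
#' @param target_bin 0-based bin to predict (within the grid).
#' @return An object of class `"state_probabilities"`: list with `probs`
#'   (length-4, summing to 1), `target_bin`, `history`.
#' @export
predict_probabilities <- function(model, history, target_bin) {
  p <- predict_case_probs(model, list(list(prior_bins = history$bin,
                                           prior_states = history$state,
                                           target_bin = target_bin)))[1, ]
  structure(list(probs = p, target_bin = target_bin, history = history),
            class = "state_probabilities")
}

#' @export
print.state_probabilities <- function(x, ...) {
  cat(sprintf("<state_probabilities> bin %d: %s\n", x$target_bin,
              paste(sprintf("p%d=%.3f", 1:4, x$probs), collapse = " ")))
  invisible(x)
}

#' Batch next-state probabilities for evaluation cases
#'
#' @param model a fitted [fit_factor_model()].
#' @param cases list of cases as built by [build_eval_cases()] (elements
#'   `prior_bins`, `prior_states`, `target_bin`).
#' @return `length(cases) x 4` matrix of probabilities, rows summing to 1.
#' @export
predict_case_probs <- function(model, cases) {
  if (is.null(model$U) || nrow(model$U) == 0) stop("empty model")
  M <- fitted(model)
  theta <- model$theta
  if (!is.finite(theta)) stop("model has non-finite theta")
  Tn <- ncol(M)
  logC <- matrix(log_kernel_const(as.vector(M), theta), nrow(M), Tn)
  out <- matrix(NA_real_, length(cases), 4)
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    tb <- cs$target_bin
    if (tb < 0 || tb >= Tn) stop("target_bin outside grid")
    js <- as.integer(cs$prior_bins) + 1L
    base <- numeric(nrow(M))
    for (k in seq_along(js)) {
      base <- base + logC[, js[k]] -
        theta * (cs$prior_states[k] - M[, js[k]])^2
    }
    lp <- vapply(1:4, function(s) {
      log_sum_exp(base + logC[, tb + 1L] - theta * (s - M[, tb + 1L])^2)
    }, numeric(1))
    lp <- lp - max(lp)
    out[i, ] <- exp(lp) / sum(exp(lp))
  }
  out
}

#' Probability thresholds for the state cascade
#'
#' @param tau2,tau3,tau4 thresholds in the open interval (0, 1) for the
#'   low-risk, high-risk and cancer states.
#' @return An object of class `"threshold_set"` (numeric vector named
#'   `tau2`, `tau3`, `tau4`).
#' @export
threshold_set <- function(tau2, tau3, tau4) {
  tau <- c(tau2 = tau2, tau3 = tau3, tau4 = tau4)
  if (any(tau <= 0 | tau >= 1))
    stop("thresholds must lie strictly inside (0, 1)")
  structure(tau, class = "threshold_set")
}

#' Threshold-cascade classification
#'
#' The states are tested in order of severity: cancer (4), then high-risk
#' (3), then low-risk (2); the first state whose probability reaches its
#' threshold is predicted, and if none does the prediction is normal (1).
#' The cascade counteracts the heavy skew toward normal results, which
#' would otherwise dominate the risk inference.
#'
#' @param probs a [predict_probabilities()] result, a length-4 vector, or
#'   an `n x 4` matrix.
#' @param tau a [threshold_set()].
#' @return Integer state(s) in 1-4.
#' @export
classify_state <- function(probs, tau) {
  p <- if (inherits(probs, "state_probabilities")) rbind(probs$probs)
       else if (is.matrix(probs)) probs else rbind(probs)
  out <- rep(1L, nrow(p))
  hit2 <- p[, 2] >= tau[["tau2"]]
  hit3 <- p[, 3] >= tau[["tau3"]]
  hit4 <- p[, 4] >= tau[["tau4"]]
  out[hit2] <- 2L
  out[hit3] <- 3L
  out[hit4] <- 4L
  if (length(out) == 1L) out[1] else out
}

#' Build prediction evaluation cases with a moving exclusion window
#'
#' For every subject and every observed bin, a case targets that bin if at
#' least two observations strictly precede `target - horizon_bins`; those
#' form the case's history, and any observations inside the window
#' `(target - horizon_bins, target)` are withheld. The window emulates
#' forecasting: no result within the forecast horizon of the target is
#' available to the model.
#'
#' @param m a [state_matrix()] of held-out histories.
#' @param horizon_bins forecast horizon in bins (>= 1); 8 bins = 2 years.
#' @return List of cases: `subject`, `target_bin`, `true_state`,
#'   `prior_bins`, `prior_states`.
#' @export
build_eval_cases <- function(m, horizon_bins) {
  stopifnot(inherits(m, "state_matrix"), horizon_bins >= 1)
  cases <- list()
  for (n in seq_len(nrow(m$values))) {
    bins <- which(m$mask[n, ]) - 1L
    if (length(bins) < 3L) next
    states <- m$values[n, bins + 1L]
    for (j in seq_along(bins)) {
      target <- bins[j]
      keep <- bins < target - horizon_bins
      if (sum(keep) < 2L) next
      cases[[length(cases) + 1L]] <- list(
        subject = m$subjects[n], target_bin = target,
        true_state = states[j], prior_bins = bins[keep],
        prior_states = states[keep])
    }
  }
  cases
}

# Precomputed per-subject index structure for fast repeated
# first-encounter computations over candidate label vectors.
label_index <- function(subjects, bins) {
  idx <- split(seq_along(subjects), subjects)
  list(idx = idx,
       bins = bins,
       last_bin = vapply(idx, function(i) max(bins[i]), numeric(1)))
}

# (time, event) pairs for state s given a label vector, using the index.
indexed_event_pairs <- function(li, labels, s) {
  time <- li$last_bin
  event <- rep(FALSE, length(li$idx))
  for (k in seq_along(li$idx)) {
    i <- li$idx[[k]]
    hit <- i[labels[i] == s]
    if (length(hit)) {
      time[k] <- min(li$bins[hit])
      event[k] <- TRUE
    }
  }
  data.frame(time = time, event = event)
}

# Eq.-style threshold objective: sum over states of the trapezoidal
# integral of |S_s - Shat_s| on the bin grid.
threshold_objective <- function(tau_vec, probs, truth_labels, subjects,
                                target_bins, times) {
  li <- label_index(subjects, target_bins)
  truth_curves <- lapply(1:4, function(s) km_survival_at(
    km_estimate(indexed_event_pairs(li, truth_labels$state, s)), times))
  threshold_objective_fast(tau_vec, probs, li, truth_curves, times)
}

threshold_objective_fast <- function(tau_vec, probs, li, truth_curves,
                                     times) {
  pred <- rep(1L, nrow(probs))
  pred[probs[, 2] >= tau_vec[1]] <- 2L
  pred[probs[, 3] >= tau_vec[2]] <- 3L
  pred[probs[, 4] >= tau_vec[3]] <- 4L
  total <- 0
  for (s in 1:4) {
    Sp <- km_survival_at(km_estimate(indexed_event_pairs(li, pred, s)),
                         times)
    total <- total + trapezoid(times, abs(truth_curves[[s]] - Sp))
  }
  total
}

trapezoid <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Minimal rand/1/bin differential evolution on a box.
diff_evolution <- function(fn, lower, upper, n_pop = 15L, n_iter = 200L,
                           F = 0.8, CR = 0.9, seed = 1L) {
  set.seed(seed)
  d <- length(lower)
  pop <- matrix(runif(n_pop * d, lower, upper), n_pop, d, byrow = TRUE)
  val <- apply(pop, 1, fn)
  for (g in seq_len(n_iter)) {
    for (i in seq_len(n_pop)) {
      idx <- sample(setdiff(seq_len(n_pop), i), 3L)
      mut <- pop[idx[1], ] + F * (pop[idx[2], ] - pop[idx[3], ])
      mut <- pmin(pmax(mut, lower), upper)
      cross <- runif(d) < CR
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, mut, pop[i, ])
      v <- fn(trial)
      if (v <= val[i]) {
        pop[i, ] <- trial
        val[i] <- v
      }
    }
    if (min(val) <= 0) break
  }
  best <- which.min(val)
  list(par = pop[best, ], value = val[best])
}

#' Fit classification thresholds by differential evolution
#'
#' Selects the cascade thresholds by minimising the summed absolute area
#' between the Kaplan-Meier curves of true first-encounter times and those
#' of the predicted labels, `sum_s int |S_s(t) - Shat_s(t)| dt`, with the
#' integral taken by the trapezoid rule on the bin grid. The search uses a
#' rand/1/bin differential-evolution scheme over `(0, 1)^3` with a fixed
#' seed.
#'
#' @param cases list from [build_eval_cases()].
#' @param probs matching `n x 4` matrix from [predict_case_probs()].
#' @param grid a [time_grid()] (for the evaluation times).
#' @param n_pop,n_iter differential-evolution population size and
#'   generations.
#' @param seed integer seed.
#' @return A [threshold_set()] with attribute `objective` (the attained
#'   objective value).
#' @export
fit_thresholds <- function(cases, probs, grid, n_pop = 15L, n_iter = 200L,
                           seed = 1L) {
  if (!length(cases)) stop("no evaluation cases")
  subjects <- vapply(cases, `[[`, character(1), "subject")
  target_bins <- vapply(cases, `[[`, numeric(1), "target_bin")
  true_states <- vapply(cases, `[[`, numeric(1), "true_state")
  if (!any(true_states > 0)) stop("no events of any state")
  missing_states <- setdiff(1:4, unique(true_states))
  if (length(missing_states))
    warning("no cases with true state ",
            paste(missing_states, collapse = ", "))
  truth_labels <- data.frame(subject = subjects, bin = target_bins,
                             state = true_states)
  times <- 0:(grid$n_bins - 1)
  eps <- 1e-6
  li <- label_index(subjects, target_bins)
  truth_curves <- lapply(1:4, function(s) km_survival_at(
    km_estimate(indexed_event_pairs(li, true_states, s)), times))
  fn <- function(tau) threshold_objective_fast(tau, probs, li,
                                               truth_curves, times)
  res <- diff_evolution(fn, lower = rep(eps, 3), upper = rep(1 - eps, 3),
                        n_pop = n_pop, n_iter = n_iter, seed = seed)
  out <- threshold_set(res$par[1], res$par[2], res$par[3])
  attr(out, "objective") <- res$value
  out
}
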