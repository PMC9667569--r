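# Direct double-sum evaluation of the next-state estimator for oracles.
enumerate_probs <- function(latent, theta, prior_bins, prior_states,
                            target_bin) {
  Cm <- function(m) 1 / sum(exp(-theta * ((1:4) - m)^2))
  w <- numeric(4)
  for (s in 1:4) {
    for (n in seq_len(nrow(latent))) {
      term <- Cm(latent[n, target_bin + 1]) *
        exp(-theta * (s - latent[n, target_bin + 1])^2)
      for (j in seq_along(prior_bins)) {
        mj <- latent[n, prior_bins[j] + 1]
        term <- term * Cm(mj) * exp(-theta * (prior_states[j] - mj)^2)
      }
      w[s] <- w[s] + term
    }
  }
  w / sum(w)
}

test_that("next-state probabilities normalise and match hand enumeration", {
  latent <- rbind(c(1.2, 1.8, 2.6, 3.1), c(1.0, 1.1, 1.3, 1.6))
  model <- toy_model(latent, theta = 2.5)
  hist <- data.frame(bin = c(0, 1), state = c(1, 2))
  p <- predict_probabilities(model, hist, target_bin = 3)
  expect_equal(sum(p$probs), 1, tolerance = 1e-12)
  expect_equal(p$probs, enumerate_probs(latent, 2.5, c(0, 1), c(1, 2), 3),
               tolerance = 1e-10)

  # single-row model with latent 1 everywhere and large theta
  m1 <- toy_model(matrix(1, 1, 4), theta = 200)
  p1 <- predict_probabilities(m1, data.frame(bin = 0, state = 1), 3)
  expect_gt(p1$probs[1], 0.999)
})

test_that("prediction is invariant to row and observation order", {
  set.seed(21)
  latent <- matrix(runif(5 * 6, 1, 4), 5, 6)
  hist <- data.frame(bin = c(0, 2, 4), state = c(1, 2, 1))
  p_ref <- predict_probabilities(toy_model(latent), hist, 5)$probs
  perm <- sample(5)
  p_rows <- predict_probabilities(toy_model(latent[perm, ]), hist, 5)$probs
  expect_equal(p_rows, p_ref, tolerance = 1e-12)
  p_obs <- predict_probabilities(toy_model(latent), hist[c(3, 1, 2), ],
                                 5)$probs
  expect_equal(p_obs, p_ref, tolerance = 1e-12)
})

test_that("an extra consensus observation never hurts the consensus state", {
  # model rows all agree on low latent values -> consensus state 1
  set.seed(22)
  latent <- matrix(runif(6 * 5, 1.0, 1.4), 6, 5)
  model <- toy_model(latent, theta = 2.5)
  base <- predict_probabilities(model, data.frame(bin = 0, state = 1), 4)
  more <- predict_probabilities(model,
                                data.frame(bin = c(0, 2), state = c(1, 1)),
                                4)
  expect_gte(more$probs[1], base$probs[1])
})

test_that("the threshold cascade fires in severity order", {
  tau <- threshold_set(0.5, 0.5, 0.5)
  expect_equal(classify_state(c(0.1, 0.1, 0.1, 0.7), tau), 4L)
  tau2 <- threshold_set(0.25, 0.5, 0.5)
  expect_equal(classify_state(c(0.4, 0.3, 0.3, 0.0), tau2), 2L)
  # nothing reaches its threshold -> normal
  expect_equal(classify_state(c(0.4, 0.2, 0.2, 0.2), tau), 1L)
  expect_error(threshold_set(0, 0.5, 0.5), "inside")
  expect_error(threshold_set(0.5, 0.5, 1), "inside")

  # monotone in tau4: raising it never converts a non-4 into a 4
  set.seed(23)
  P <- matrix(runif(400), 100, 4); P <- P / rowSums(P)
  lo <- classify_state(P, threshold_set(0.3, 0.3, 0.3))
  hi <- classify_state(P, threshold_set(0.3, 0.3, 0.6))
  expect_true(all(!(lo != 4L & hi == 4L)))
})

test_that("evaluation cases respect the moving exclusion window", {
  g <- time_grid(24)
  m <- load_histories(data.frame(
    subject = c("A", "B", "B", "B", "B"),
    bin = c(3, 0, 4, 15, 20), state = c(1, 1, 2, 3, 1)), g)
  # subject A has a single observation: no cases
  cases <- build_eval_cases(m, horizon_bins = 8)
  expect_true(all(vapply(cases, `[[`, character(1), "subject") == "B"))
  # B targets: bin 15 (priors {0,4} < 7? no, 15-8=7 -> {0,4}), bin 20
  targets <- vapply(cases, `[[`, numeric(1), "target_bin")
  expect_setequal(targets, c(15, 20))
  c20 <- cases[[which(targets == 20)]]
  # horizon window (12, 20) removes the bin-15 observation
  expect_equal(c20$prior_bins, c(0, 4))
  expect_equal(c20$prior_states, c(1L, 2L))
  expect_equal(c20$true_state, 1L)

  empty <- state_matrix(matrix(NA_integer_, 2, 24),
                        matrix(FALSE, 2, 24), g)
  expect_length(build_eval_cases(empty, 8), 0)
})

test_that("threshold fitting attains zero for a perfect classifier", {
  # engineered probabilities: mass 1 on the true state
  set.seed(24)
  n <- 60
  subj <- as.character(rep(1:20, each = 3))
  bins <- rep(c(2, 6, 10), 20)
  states <- sample(1:4, n, replace = TRUE, prob = c(0.6, 0.2, 0.15, 0.05))
  cases <- lapply(seq_len(n), function(i) {
    list(subject = subj[i], target_bin = bins[i], true_state = states[i],
         prior_bins = 0, prior_states = 1)
  })
  probs <- matrix(0, n, 4)
  probs[cbind(seq_len(n), states)] <- 1
  tau <- fit_thresholds(cases, probs, time_grid(12), n_pop = 10,
                        n_iter = 30, seed = 3)
  expect_equal(attr(tau, "objective"), 0)
  expect_true(all(tau > 0 & tau < 1))
})

test_that("fitted thresholds beat random threshold draws", {
  set.seed(25)
  n <- 80
  subj <- as.character(rep(1:20, each = 4))
  bins <- rep(c(2, 5, 8, 11), 20)
  states <- sample(1:4, n, replace = TRUE, prob = c(0.5, 0.25, 0.15, 0.1))
  cases <- lapply(seq_len(n), function(i) {
    list(subject = subj[i], target_bin = bins[i], true_state = states[i],
         prior_bins = 0, prior_states = 1)
  })
  # noisy probabilities correlated with the truth
  probs <- matrix(runif(n * 4), n, 4)
  probs[cbind(seq_len(n), states)] <- probs[cbind(seq_len(n), states)] + 1
  probs <- probs / rowSums(probs)
  g <- time_grid(12)
  tau <- fit_thresholds(cases, probs, g, n_pop = 15, n_iter = 60, seed = 4)
  obj <- function(tv) screenmf:::threshold_objective(
    tv, probs,
    data.frame(subject = subj, bin = bins, state = states),
    subj, bins, 0:11)
  best_random <- min(vapply(1:20, function(i) obj(runif(3)), numeric(1)))
  expect_lte(attr(tau, "objective"), best_random + 1e-12)
})
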