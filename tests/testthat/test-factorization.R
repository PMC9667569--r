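test_that("regularizer operators match their closed forms", {
  reg <- make_regularizer("difference", 5)
  expect_equal(dim(reg$matrix), c(4L, 5L))
  expect_equal(as.vector(reg$matrix %*% rep(3, 5)), rep(0, 4))
  reg3 <- make_regularizer("difference", 3)
  expect_equal(as.vector(reg3$matrix %*% c(1, 3, 6)), c(2, 3))

  damp <- make_regularizer("damped_difference", 4, gamma = 1)
  D <- make_regularizer("difference", 4)$matrix
  K <- exp(-abs(outer(1:3, 1:3, "-")))
  expect_equal(damp$matrix, K %*% D)
  expect_equal(K[1, 2], exp(-1))
  expect_error(make_regularizer("damped_difference", 4, gamma = NULL),
               "gamma")

  # gamma -> Inf approaches the plain difference operator
  far <- make_regularizer("damped_difference", 6, gamma = 50)
  expect_lt(max(abs(far$matrix - make_regularizer("difference", 6)$matrix)),
            1e-6)
})

test_that("damped objective converges to the plain one as gamma grows", {
  m <- random_state_matrix(6, 10, 0.5, seed = 4)
  W <- build_weights(m, "uniform")
  set.seed(1)
  model <- list(U = matrix(rnorm(12), 6, 2), V = matrix(rnorm(20), 10, 2),
                shifts = integer(6),
                config = factorization_config(rank = 2))
  model$regularizer <- make_regularizer("damped_difference", 10, gamma = 50)
  o_damped <- objective_value(m, W, model)
  model$regularizer <- make_regularizer("difference", 10)
  o_plain <- objective_value(m, W, model)
  expect_lt(abs(o_damped - o_plain) / o_plain, 1e-6)
})

test_that("weights are zero off the mask in every mode", {
  m <- random_state_matrix(5, 8, 0.4, seed = 7)
  W <- build_weights(m, "uniform")
  expect_equal(W, matrix(as.numeric(m$mask), 5, 8), ignore_attr = TRUE)

  # printed-formula arithmetic: confidence 1, propensity 0.5 -> weight 2
  P <- matrix(0.5, 5, 8)
  W2 <- build_weights(m, "inverse_propensity", propensity = P,
                      state_confidence = rep(1, 4))
  expect_equal(unique(W2[m$mask]), 2)
  expect_true(all(W2[!m$mask] == 0))
  expect_error(build_weights(m, "inverse_propensity",
                             propensity = matrix(0, 5, 8)),
               "positive")
  # default (smoothed column frequency) propensities are positive on mask
  W3 <- build_weights(m, "inverse_propensity")
  expect_true(all(W3[m$mask] > 0) && all(W3[!m$mask] == 0))
})

test_that("objective matches a term-by-term summation oracle", {
  for (seed in 1:5) {
    m <- random_state_matrix(3, 4, 0.6, seed = seed)
    W <- build_weights(m, "uniform")
    W[m$mask] <- runif(sum(m$mask), 0.5, 2)
    set.seed(seed)
    model <- list(U = matrix(rnorm(6), 3, 2), V = matrix(rnorm(8), 4, 2),
                  shifts = c(-1L, 0L, 2L),
                  config = factorization_config(
                    rank = 2, reg_coefficients = c(0.3, 0.7, 1.2)),
                  regularizer = make_regularizer("damped_difference", 4,
                                                 gamma = 0.8))
    for (bnd in c("replicate", "zero")) {
      model$config$shift_boundary <- bnd
      expect_equal(
        objective_value(m, W, model),
        loop_objective(m$values, m$mask, W, model$U, model$V,
                       model$shifts, c(0.3, 0.7, 1.2),
                       model$regularizer$matrix, boundary = bnd))
    }
  }
})

test_that("objective reduces to the weighted data term at U = V = 0", {
  m <- random_state_matrix(4, 6, 0.5, seed = 2)
  W <- build_weights(m, "uniform")
  model <- list(U = matrix(0, 4, 2), V = matrix(0, 6, 2),
                shifts = integer(4),
                config = factorization_config(rank = 2),
                regularizer = make_regularizer("difference", 6))
  expect_equal(objective_value(m, W, model),
               sum(m$values[m$mask]^2))
})

test_that("coefficient update solves the row-wise ridge problems exactly", {
  set.seed(3)
  Y <- matrix(rnorm(8 * 6), 8, 6)  # fully observed, real-valued
  W <- matrix(1, 8, 6)
  V <- qr.Q(qr(matrix(rnorm(6 * 2), 6, 2)))  # orthonormal columns
  U <- update_coefficients(Y, W, V, beta1 = 0)
  expect_equal(U, Y %*% V)

  # beta1 -> Inf shrinks U to zero
  U_big <- update_coefficients(Y, W, V, beta1 = 1e12)
  expect_lt(max(abs(U_big)), 1e-9)

  # stationarity of the weighted, shifted problem
  m <- random_state_matrix(5, 9, 0.6, seed = 5)
  W <- build_weights(m, "uniform"); W[m$mask] <- runif(sum(m$mask), 0.5, 2)
  V <- matrix(rnorm(18), 9, 2)
  sh <- c(-2L, 0L, 1L, 0L, 3L)
  U <- update_coefficients(m, W, V, shifts = sh, beta1 = 0.5)
  d <- screenmf:::as_numeric_data(m)
  for (n in 1:5) {
    g <- 2 * 0.5 * U[n, ]
    for (t in 1:9) {
      if (!m$mask[n, t]) next
      ts <- min(max(t - sh[n], 1), 9)
      r <- d$Y[n, t] - sum(U[n, ] * V[ts, ])
      g <- g - 2 * W[n, t]^2 * r * V[ts, ]
    }
    expect_lt(sqrt(sum(g^2)), 1e-8 * (1 + sqrt(sum(U^2))))
  }

  # degenerate row with beta1 = 0 is rejected with advice
  m1 <- state_matrix(matrix(c(2, rep(NA, 5)), 1, 6),
                     matrix(c(TRUE, rep(FALSE, 5)), 1, 6), time_grid(6))
  expect_error(
    update_coefficients(m1, build_weights(m1, "uniform"),
                        matrix(rnorm(12), 6, 2), beta1 = 0),
    "beta1")
})

test_that("profile update solves the stacked system exactly", {
  set.seed(4)
  Y <- matrix(rnorm(10 * 6), 10, 6)
  W <- matrix(1, 10, 6)
  U <- qr.Q(qr(matrix(rnorm(10 * 2), 10, 2)))
  reg <- make_regularizer("difference", 6)
  V <- update_profiles(Y, W, U, beta2 = 0, beta3 = 0, regularizer = reg)
  expect_equal(V, t(Y) %*% U)

  V_big <- update_profiles(Y, W, U, beta2 = 1e12, beta3 = 0,
                           regularizer = reg)
  expect_lt(max(abs(V_big)), 1e-9)

  # stationarity with weights, shifts, and the damped regularizer
  m <- random_state_matrix(6, 8, 0.5, seed = 6)
  W <- build_weights(m, "uniform"); W[m$mask] <- runif(sum(m$mask), 0.5, 2)
  U <- matrix(rnorm(12), 6, 2)
  sh <- c(0L, -1L, 2L, 0L, 1L, 0L)
  reg <- make_regularizer("damped_difference", 8, gamma = 1)
  V <- update_profiles(m, W, U, shifts = sh, beta2 = 0.4, beta3 = 0.9,
                       regularizer = reg)
  # numerical gradient of the quadratic subproblem must vanish
  d <- screenmf:::as_numeric_data(m)
  fn <- function(v) {
    Vm <- matrix(v, 8, 2)
    loop_objective(d$Y, m$mask, W, U, Vm, sh, c(0, 0.4, 0.9), reg$matrix)
  }
  g <- numDeriv_grad(fn, as.vector(V))
  expect_lt(sqrt(sum(g^2)), 1e-6 * (1 + sqrt(sum(V^2))))
})

test_that("shift search enumerates and breaks ties toward zero", {
  m <- random_state_matrix(3, 10, 0.7, seed = 8)
  W <- build_weights(m, "uniform")
  U <- matrix(rnorm(6), 3, 2)
  V <- matrix(rnorm(20), 10, 2)
  expect_equal(search_shifts(m, W, U, V, 0), rep(0L, 3))
  expect_error(search_shifts(m, W, U, V, 13))

  # a row that is exactly a profile shifted by +2 is recovered
  Tn <- 30
  prof <- exp(-0.05 * (seq_len(Tn) - 10)^2)
  Y <- rbind(c(rep(0, 2), prof[1:(Tn - 2)]))  # shifted forward 2 bins
  W1 <- matrix(1, 1, Tn)
  z <- screenmf:::cpp_search_shifts(Y, W1, matrix(1, 1, 1),
                                    cbind(prof), 4L, TRUE)
  expect_equal(as.integer(z), 2L)

  # constant profile: all candidates tie, zero wins
  Yc <- matrix(1, 1, 10)
  zc <- screenmf:::cpp_search_shifts(Yc, matrix(1, 1, 10), matrix(1, 1, 1),
                                     cbind(rep(1, 10)), 3L, TRUE)
  expect_equal(as.integer(zc), 0L)
})

test_that("fit recovers a noiseless low-rank matrix and descends monotonically", {
  set.seed(9)
  u <- runif(12, 0.5, 2); v <- runif(15, 0.5, 2)
  Y <- outer(u, v)  # rank-1, fully observed
  cfg <- factorization_config(rank = 1,
                              reg_coefficients = c(1e-8, 1e-8, 1e-8),
                              max_iter = 200, seed = 1)
  model <- fit_factor_model(Y, cfg)
  expect_lt(norm(fitted(model) - Y, "F") / norm(Y, "F"), 1e-3)
  expect_true(model$converged)

  # monotone objective trace on a sparse discrete fixture
  m <- random_state_matrix(10, 12, 0.5, seed = 10)
  fit1 <- fit_factor_model(m, variant_config("SCMF", rank = 2,
                                             max_iter = 100, seed = 2))
  o <- fit1$objective
  expect_true(all(diff(o) <= 1e-10 * abs(o[-length(o)])))

  # determinism: same seed, identical model
  fit2 <- fit_factor_model(m, variant_config("SCMF", rank = 2,
                                             max_iter = 100, seed = 2))
  expect_identical(fit1$U, fit2$U)
  expect_identical(fit1$V, fit2$V)
  expect_identical(fit1$shifts, fit2$shifts)
})

test_that("theta MLE follows the closed form and its scaling law", {
  # 4 observed cells, all residuals +/-1 -> theta* = 4 / (2 * 4) = 0.5
  g <- time_grid(4)
  m <- state_matrix(matrix(c(2, 3, 2, 3), 1, 4), matrix(TRUE, 1, 4), g)
  M <- matrix(c(3, 2, 3, 2), 1, 4)
  expect_equal(mle_theta(m, M), 0.5)
  # residuals doubled -> theta quartered
  M2 <- matrix(c(4, 1, 4, 1), 1, 4)
  expect_equal(mle_theta(m, M2), 0.125)
  # zero residuals are degenerate
  expect_error(mle_theta(m, matrix(c(2, 3, 2, 3), 1, 4)), "degenerate")
})

test_that("reconstruction error is the MSE over unobserved cells", {
  set.seed(11)
  M <- matrix(rnorm(30), 5, 6)
  mask <- matrix(runif(30) < 0.4, 5, 6)
  expect_equal(reconstruction_error(M, M, mask), 0)
  # constant residual c on unobserved cells -> c^2
  Mh <- M + 0.7 * !mask
  expect_equal(reconstruction_error(M, Mh, mask), 0.49)
  # loop oracle
  Mh2 <- M + matrix(rnorm(30), 5, 6)
  acc <- 0; cnt <- 0
  for (i in 1:5) for (j in 1:6) if (!mask[i, j]) {
    acc <- acc + (M[i, j] - Mh2[i, j])^2; cnt <- cnt + 1
  }
  expect_equal(reconstruction_error(M, Mh2, mask), acc / cnt)
  expect_error(reconstruction_error(M, Mh, matrix(TRUE, 5, 6)),
               "unobserved")
})

test_that("fitting shift-consistent data matches the generating model", {
  # all rows share one profile shifted by a common offset; the fitted
  # latent matrix should explain the observed cells as well as the truth
  set.seed(12)
  Tn <- 40
  prof <- 1 + 3 * exp(-0.02 * (seq_len(Tn) - 15)^2)
  N <- 30
  z_true <- rep(2L, N)
  Y <- matrix(NA_real_, N, Tn)
  amp <- runif(N, 0.6, 1.4)
  for (n in 1:N) {
    shifted <- c(rep(NA, z_true[n]), amp[n] * prof)[1:Tn]
    keep <- runif(Tn) < 0.5
    Y[n, keep] <- shifted[keep]
  }
  cfg <- variant_config("SCMF", rank = 1,
                        reg_coefficients = c(1e-6, 1e-6, 1e-6),
                        max_iter = 300, seed = 3)
  model <- suppressWarnings(fit_factor_model(Y, cfg))
  mask <- !is.na(Y)
  Y0 <- ifelse(mask, Y, 0)
  fit_disc <- sum((Y0 - fitted(model))[mask]^2)
  truth <- matrix(NA_real_, N, Tn)
  for (n in 1:N)
    truth[n, ] <- c(rep(amp[n] * prof[1], z_true[n]),
                    amp[n] * prof)[1:Tn]
  truth_disc <- sum((Y0 - truth)[mask]^2)
  expect_lt(fit_disc, max(truth_disc, 1e-8) * 1.01)
})
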