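# Shared fixture builders for the test suite.

# Random sparse state matrix with at least one observation per row.
random_state_matrix <- function(N = 5, Tn = 8, density = 0.5, seed = 1) {
  set.seed(seed)
  mask <- matrix(runif(N * Tn) < density, N, Tn)
  for (n in which(rowSums(mask) == 0)) mask[n, sample.int(Tn, 1)] <- TRUE
  v <- matrix(sample(1:4, N * Tn, replace = TRUE), N, Tn)
  state_matrix(v, mask, time_grid(Tn))
}

# Small deterministic model for prediction tests: latent rows supplied
# directly (U = rows, V = identity-ish), no shifts.
toy_model <- function(latent, theta = 2.5) {
  structure(list(U = latent, V = diag(ncol(latent)),
                 shifts = integer(nrow(latent)), theta = theta,
                 config = factorization_config(rank = ncol(latent)),
                 regularizer = make_regularizer("difference", ncol(latent)),
                 grid = time_grid(ncol(latent))),
            class = "factor_model")
}

# Random survival pairs (possibly tied, non-integer censoring times).
random_pairs <- function(n = 20, seed = 1) {
  set.seed(seed)
  data.frame(time = sample(c(1:8, 2.5, 4.5), n, replace = TRUE),
             event = runif(n) < 0.6)
}

# Central-difference numerical gradient.
numDeriv_grad <- function(fn, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (fn(x + e) - fn(x - e)) / (2 * h)
  }, numeric(1))
}

# Brute-force penalized objective by explicit summation (independent of
# the package's linear-algebra path).
loop_objective <- function(Y, mask, W, U, V, shifts, coefs, Rmat,
                           boundary = "replicate") {
  N <- nrow(Y); Tn <- ncol(Y); r <- ncol(U)
  total <- 0
  for (n in 1:N) for (t in 1:Tn) {
    if (!mask[n, t]) next
    ts <- t - shifts[n]
    m <- if (ts >= 1 && ts <= Tn) sum(U[n, ] * V[ts, ])
         else if (boundary == "replicate")
           sum(U[n, ] * V[min(max(ts, 1), Tn), ])
         else 0
    total <- total + (W[n, t] * (Y[n, t] - m))^2
  }
  as.numeric(total + coefs[1] * sum(U^2) + coefs[2] * sum(V^2) +
               coefs[3] * sum((Rmat %*% V)^2))
}
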