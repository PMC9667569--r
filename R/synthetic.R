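#' Default per-bin observation probabilities
#'
#' The masking process emulates the screening programme's recall pattern:
#' after a normal result women are recalled triennially (with partial
#' adherence, about 1 chance in 20 of a result in any 3-month bin), while
#' abnormal results trigger follow-up exams within roughly a year. The
#' entries are the
#' per-bin probability of observing a result given the most recent
#' *observed* state (`"none"` before the first observation). Registry
#' observation probabilities are not public; these stand-ins are calibrated
#' to give roughly 8% overall density on registry-like simulations.
#'
#' @return Named numeric vector with entries `none`, `1`, `2`, `3`, `4`.
#' @export
default_observation_table <- function() {
  c(none = 0.05, `1` = 0.05, `2` = 0.25, `3` = 0.35, `4` = 0.35)
}

#' Configuration of the synthetic screening-history generator
#'
#' The generator draws latent risk profiles as non-negative combinations
#' `M = U V'` of `n_profiles` smooth basic profiles
#' `V[t, k] = exp(-1e-3 (t - mu_k)^2)` with coefficients `U[n, k] ~ Exp(1)`,
#' maps them to discrete states 1-4 through the Gaussian observation kernel
#' at reliability `theta`, and then thins the complete state matrix with a
#' state-dependent observation process.
#'
#' @param n_subjects number of rows `N`.
#' @param n_bins number of 3-month bins `T`.
#' @param n_profiles number of basic profiles `K` (default 5).
#' @param profile_centers bin positions `mu_k` of the profile peaks;
#'   default evenly spaced across the first quarter of the grid. The
#'   bumps are wide (length scale ~22 bins), so concentrating them in the
#'   early screening ages -- where HPV acquisition and lesion incidence
#'   peak -- leaves most of the grid near the baseline and reproduces the
#'   registry's normal-state majority; centers spread across the whole
#'   axis would place every cell under a bump and destroy the imbalance.
#' @param theta observation-kernel reliability (default 2.5).
#' @param rescale_latent if `TRUE` (default) `M` is affinely mapped onto
#'   `[1, 4]` before discretisation, so all four states are reachable.
#' @param observation_table per-bin observation probabilities conditioned
#'   on the last observed state; see [default_observation_table()].
#' @param target_density optional overall observed fraction; the
#'   observation table is rescaled so the expected density matches it.
#' @param discretize `"sample"` (default) draws states from the kernel's
#'   categorical distribution; `"argmax"` takes the modal state.
#' @param seed integer seed driving every random stage.
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_subjects, n_bins, n_profiles = 5L,
                             profile_centers = NULL, theta = 2.5,
                             rescale_latent = TRUE,
                             observation_table = default_observation_table(),
                             target_density = NULL,
                             discretize = c("sample", "argmax"),
                             seed = 1L) {
  stopifnot(n_subjects >= 1, n_bins >= 2, n_profiles >= 1, theta > 0)
  if (is.null(profile_centers))
    profile_centers <- seq(0, (n_bins - 1) / 4, length.out = n_profiles)
  if (length(profile_centers) != n_profiles)
    stop("need one center per profile")
  if (any(profile_centers < 0 | profile_centers >= n_bins))
    stop("profile centers must lie in [0, n_bins)")
  need <- c("none", "1", "2", "3", "4")
  if (!all(need %in% names(observation_table)))
    stop("observation_table needs entries ", paste(need, collapse = ", "))
  if (any(observation_table < 0 | observation_table > 1))
    stop("observation probabilities must lie in [0, 1]")
  structure(
    list(n_subjects = as.integer(n_subjects), n_bins = as.integer(n_bins),
         n_profiles = as.integer(n_profiles),
         profile_centers = profile_centers, theta = theta,
         rescale_latent = isTRUE(rescale_latent),
         observation_table = observation_table[need],
         target_density = target_density,
         discretize = match.arg(discretize), seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Smooth basic temporal profiles
#'
#' `V[t, k] = exp(-1e-3 (t - mu_k)^2)`: Gaussian bumps (length scale about
#' 22 bins, i.e. 5-6 years) peaking at the given centers.
#'
#' @param grid a [time_grid()].
#' @param centers peak positions (bins, 0-based), within `[0, n_bins)`.
#' @return `T x K` matrix with entries in `(0, 1]`; column `k` attains 1 at
#'   `t = centers[k]`.
#' @export
make_basic_profiles <- function(grid, centers) {
  Tn <- grid$n_bins
  if (any(centers < 0 | centers >= Tn))
    stop("centers must lie in [0, n_bins)")
  t <- seq_len(Tn) - 1
  vapply(centers, function(mu) exp(-1e-3 * (t - mu)^2), numeric(Tn))
}

#' Subject-specific profile coefficients
#'
#' i.i.d. unit-rate exponential draws, giving non-negative mixing weights.
#'
#' @param n,k matrix dimensions.
#' @param seed integer seed.
#' @return `n x k` non-negative matrix.
#' @export
sample_coefficients <- function(n, k, seed = 1L) {
  stopifnot(n >= 1, k >= 1)
  set.seed(seed)
  matrix(rexp(n * k, rate = 1), n, k)
}

# Per-cell categorical probabilities of the 4 states given latent values.
# Returns a length(m) x 4 matrix of normalised kernel masses.
state_kernel_probs <- function(m, theta) {
  p <- vapply(1:4, function(s) exp(-theta * (s - m)^2), numeric(length(m)))
  p <- matrix(p, ncol = 4)
  p / rowSums(p)
}

#' Discretise a latent matrix into screening states
#'
#' Each cell is mapped to a state in 1-4 through the Gaussian observation
#' kernel `p(s | m) = C_m exp(-theta (s - m)^2)` normalised over the four
#' states: by sampling from this categorical distribution (default) or by
#' taking its mode.
#'
#' @param latent numeric matrix of latent values.
#' @param theta kernel reliability (> 0); larger values concentrate the
#'   states around the latent value.
#' @param seed integer seed (sampling mode).
#' @param method `"sample"` or `"argmax"`.
#' @return Integer matrix of the same shape with entries in 1-4.
#' @export
discretize_states <- function(latent, theta, seed = 1L,
                              method = c("sample", "argmax")) {
  stopifnot(theta > 0)
  method <- match.arg(method)
  p <- state_kernel_probs(as.vector(latent), theta)
  s <- if (method == "argmax") {
    max.col(p, ties.method = "first")
  } else {
    set.seed(seed)
    u <- runif(nrow(p))
    cp <- p %*% upper.tri(diag(4), diag = TRUE)  # row-wise cumulative sums
    1L + rowSums(u > cp[, -4, drop = FALSE])
  }
  matrix(as.integer(s), nrow(latent), ncol(latent))
}

# Exact expected density of the masking chain by forward dynamic
# programming over the distribution of the last observed state.
expected_mask_density <- function(full, table) {
  N <- nrow(full); Tn <- ncol(full)
  p_of <- function(last) table[[as.character(last)]]
  total <- 0
  for (n in seq_len(N)) {
    # q[l]: P(last observed state == l), l in (none, 1..4)
    q <- c(1, 0, 0, 0, 0)
    names(q) <- c("none", "1", "2", "3", "4")
    for (t in seq_len(Tn)) {
      pk <- sum(q * table[names(q)])
      total <- total + pk
      s <- as.character(full[n, t])
      # kept mass moves to state s
      q <- q * (1 - table[names(q)])
      q[s] <- q[s] + pk
    }
  }
  total / (N * Tn)
}

# Rescale the observation table (probabilities capped at 1) so the expected
# density of the masking chain equals `target`.
rescale_observation_table <- function(full, table, target) {
  if (target > 1) stop("target_density must be <= 1")
  if (target == 0) return(table * 0)
  f <- function(c) expected_mask_density(full, pmin(c * table, 1)) - target
  hi <- 1
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
  if (f(hi) < 0) stop("target_density ", target, " is not achievable")
  c_star <- stats::uniroot(f, c(0, hi), tol = 1e-6)$root
  pmin(c_star * table, 1)
}

#' Thin a complete state matrix with a state-dependent observation process
#'
#' Scans each row left to right; at each bin the entry is kept with the
#' probability the observation table assigns to the most recent *kept*
#' state (`"none"` before the first kept entry). This reproduces the
#' registry pattern of long triennial gaps after normal results and dense
#' follow-up after abnormal ones.
#'
#' @param full integer matrix of complete states (entries 1-4).
#' @param observation_table named probabilities; see
#'   [default_observation_table()].
#' @param target_density optional overall density to calibrate the table to
#'   (expected, computed exactly by forward recursion).
#' @param seed integer seed.
#' @param grid optional [time_grid()]; defaults to `ncol(full)` bins.
#' @return A [state_matrix()] whose mask marks the kept entries.
#' @export
mask_states <- function(full, observation_table = default_observation_table(),
                        target_density = NULL, seed = 1L, grid = NULL) {
  full <- as.matrix(full)
  if (is.null(grid)) grid <- time_grid(ncol(full))
  tab <- observation_table
  if (!is.null(target_density))
    tab <- rescale_observation_table(full, tab, target_density)
  set.seed(seed)
  N <- nrow(full); Tn <- ncol(full)
  u <- matrix(runif(N * Tn), N, Tn)
  mask <- matrix(FALSE, N, Tn)
  for (n in seq_len(N)) {
    last <- "none"
    for (t in seq_len(Tn)) {
      if (u[n, t] < tab[[last]]) {
        mask[n, t] <- TRUE
        last <- as.character(full[n, t])
      }
    }
  }
  state_matrix(full, mask, grid)
}

#' Generate a synthetic screening dataset
#'
#' Runs the full generative pipeline: basic profiles and exponential
#' coefficients form the latent matrix `M = U V'` (affinely rescaled onto
#' `[1, 4]` when configured), which is discretised through the observation
#' kernel and thinned by the state-dependent masking process. All stages
#' are seeded deterministically from `config$seed`, so the generator is a
#' pure function of its configuration.
#'
#' @param config a [synthetic_config()].
#' @return An object of class `"synthetic_dataset"`: list with `latent`
#'   (`N x T` ground-truth matrix), `full_states` (complete integer
#'   matrix), `observed` (the masked [state_matrix()]), and `config`.
#' @export
generate_screening_data <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  grid <- time_grid(config$n_bins)
  V <- make_basic_profiles(grid, config$profile_centers)
  U <- sample_coefficients(config$n_subjects, config$n_profiles,
                           seed = config$seed)
  M <- U %*% t(V)
  if (config$rescale_latent) {
    rng <- range(M)
    if (rng[2] > rng[1]) M <- 1 + 3 * (M - rng[1]) / (rng[2] - rng[1])
    else M[] <- 2.5
  }
  full <- discretize_states(M, config$theta, seed = config$seed + 1L,
                            method = config$discretize)
  observed <- mask_states(full, config$observation_table,
                          target_density = config$target_density,
                          seed = config$seed + 2L, grid = grid)
  structure(list(latent = M, full_states = full, observed = observed,
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  tab <- table(factor(x$full_states, levels = 1:4))
  cat(sprintf(
    "<synthetic_dataset> %d x %d, density %.3f, state mix %s\n",
    nrow(x$latent), ncol(x$latent), density(x$observed),
    paste(sprintf("%d:%.2f", 1:4, tab / sum(tab)), collapse = " ")))
  invisible(x)
}
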