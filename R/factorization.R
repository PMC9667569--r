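#' Temporal regularization operator for the basic profiles
#'
#' Two choices of the operator `R` in the penalty `||R V||_F^2`:
#' the forward difference matrix `R = D` (entries -1, +1 on adjacent
#' positions), enforcing strong temporal smoothness, and the damped
#' difference `R = K D` with `K` the Toeplitz matrix
#' `K[i, j] = exp(-gamma |i - j|)`. The damped form penalises variation at
#' fast time scales less, allowing the larger local variability seen after
#' abnormal screening results; as `gamma -> Inf` it approaches plain `D`.
#'
#' @param kind `"difference"` or `"damped_difference"`.
#' @param grid a [time_grid()] (or an integer number of bins `T`).
#' @param gamma damping rate in inverse bins (damped kind only; default 1).
#' @return An object of class `"regularizer"`: list with `kind`, `matrix`
#'   (`(T-1) x T`), and `gamma`.
#' @export
make_regularizer <- function(kind = c("difference", "damped_difference"),
                             grid, gamma = 1) {
  kind <- match.arg(kind)
  Tn <- if (inherits(grid, "time_grid")) grid$n_bins else as.integer(grid)
  if (Tn < 2) stop("need at least 2 bins")
  D <- diff(diag(Tn))  # (T-1) x T forward differences
  if (kind == "difference") {
    R <- D
    gamma <- NULL
  } else {
    if (is.null(gamma) || !is.finite(gamma) || gamma <= 0)
      stop("damped_difference requires gamma > 0")
    i <- seq_len(Tn - 1)
    K <- exp(-gamma * abs(outer(i, i, "-")))
    R <- K %*% D
  }
  structure(list(kind = kind, matrix = R, gamma = gamma),
            class = "regularizer")
}

#' Discrepancy weights for the factorization
#'
#' Builds the weight matrix `W`: zero off the observed set, strictly
#' positive on it. `"uniform"` gives unit weights. `"inverse_propensity"`
#' gives `confidence(s) / propensity(n, t)`, down-weighting cells that were
#' likely to be observed anyway (entries are not missing at random: women
#' with abnormal results are recalled sooner). By default the propensity is
#' the column-wise observed fraction smoothed by a short moving average,
#' and the per-state confidence is 1.
#'
#' @param m a [state_matrix()].
#' @param mode `"uniform"`, `"inverse_propensity"`, or `"custom"`.
#' @param propensity optional `N x T` matrix or length-`T` vector of
#'   observation propensities (strictly positive where observed).
#' @param state_confidence optional length-4 positive vector of per-state
#'   result confidences.
#' @param weights custom `N x T` non-negative matrix (`mode = "custom"`);
#'   must be positive exactly on the mask.
#' @return `N x T` numeric weight matrix.
#' @export
build_weights <- function(m, mode = c("uniform", "inverse_propensity",
                                      "custom"),
                          propensity = NULL, state_confidence = NULL,
                          weights = NULL) {
  mode <- match.arg(mode)
  N <- nrow(m$values); Tn <- ncol(m$values)
  if (mode == "uniform")
    return(matrix(as.numeric(m$mask), N, Tn))
  if (mode == "custom") {
    if (is.null(weights)) stop("custom mode needs `weights`")
    weights <- as.matrix(weights)
    if (any(weights[m$mask] <= 0) || any(weights[!m$mask] != 0))
      stop("custom weights must be positive exactly on the observed set")
    return(weights)
  }
  if (is.null(propensity)) {
    colfrac <- colMeans(m$mask)
    # moving-average smoothing over +/- 2 bins
    sm <- stats::filter(colfrac, rep(1 / 5, 5), sides = 2)
    sm[is.na(sm)] <- colfrac[is.na(sm)]
    propensity <- pmax(as.numeric(sm), 1e-3)
  }
  P <- if (is.matrix(propensity)) propensity
       else matrix(propensity, N, Tn, byrow = TRUE)
  if (any(P[m$mask] <= 0)) stop("propensities must be strictly positive")
  if (is.null(state_confidence)) state_confidence <- rep(1, 4)
  if (any(state_confidence <= 0)) stop("state confidences must be positive")
  W <- matrix(0, N, Tn)
  W[m$mask] <- state_confidence[m$values[m$mask]] / P[m$mask]
  W
}

#' Factorization configuration and named model variants
#'
#' `factorization_config()` collects the hyper-parameters of the
#' variational problem: rank, the three penalty coefficients, the temporal
#' regularizer, the discrepancy weight mode, and the shift search bound.
#' `variant_config()` returns the five named presets used in numerical
#' experiments: `MF` (plain difference regularizer), `CMF` (damped
#' difference), `WCMF` (damped + inverse-propensity weights), `SCMF`
#' (damped + shifts up to 3 years), and `SWCMF` (all three; also written
#' WSCMF).
#'
#' @param rank factorization rank `r` (>= 1, far below `min(N, T)`).
#' @param reg_coefficients penalty coefficients `(b1, b2, b3)` on
#'   `||U||_F^2`, `||V||_F^2`, `||R V||_F^2`; non-negative. Not reported in
#'   the source experiments; defaults to `c(1, 1, 1)`.
#' @param regularizer_kind `"difference"` or `"damped_difference"`.
#' @param gamma damping rate for the damped regularizer (default 1).
#' @param weight_mode `"uniform"`, `"inverse_propensity"`, or `"custom"`.
#' @param max_shift_bins shift search bound in bins; 12 bins = 3 years for
#'   the shifted variants, 0 disables shifting.
#' @param shift_boundary handling of cells pushed outside the grid by a
#'   shift: `"replicate"` (default) carries the profile edge value into
#'   the uncovered bins, `"zero"` assigns latent value 0 there (the
#'   literal 0/1 diagonal shift matrix). Replication is the default
#'   because a latent risk profile takes values on the state scale
#'   `[1, 4]`; scoring uncovered bins at 0 puts them far below any valid
#'   state and lets boundary artifacts dominate the reconstruction error
#'   of shifted models.
#' @param tol stopping threshold on the relative change of the latent
#'   matrix between sweeps (default 1e-6).
#' @param max_iter maximum number of alternating sweeps.
#' @param seed integer seed for the random profile initialisation.
#' @return An object of class `"factorization_config"`.
#' @export
factorization_config <- function(rank = 5L, reg_coefficients = c(1, 1, 1),
                                 regularizer_kind = c("damped_difference",
                                                      "difference"),
                                 gamma = 1, weight_mode = c("uniform",
                                                            "inverse_propensity",
                                                            "custom"),
                                 max_shift_bins = 0L,
                                 shift_boundary = c("replicate", "zero"),
                                 tol = 1e-6, max_iter = 500L, seed = 1L) {
  stopifnot(rank >= 1, length(reg_coefficients) == 3,
            all(reg_coefficients >= 0), tol > 0, max_iter >= 1,
            max_shift_bins >= 0, max_shift_bins <= 12)
  structure(
    list(rank = as.integer(rank), reg_coefficients = reg_coefficients,
         regularizer_kind = match.arg(regularizer_kind), gamma = gamma,
         weight_mode = match.arg(weight_mode),
         max_shift_bins = as.integer(max_shift_bins),
         shift_boundary = match.arg(shift_boundary), tol = tol,
         max_iter = as.integer(max_iter), seed = as.integer(seed)),
    class = "factorization_config"
  )
}

#' @rdname factorization_config
#' @param variant one of `"MF"`, `"CMF"`, `"WCMF"`, `"SCMF"`, `"SWCMF"`.
#' @param ... overrides passed on to [factorization_config()].
#' @export
variant_config <- function(variant = c("MF", "CMF", "WCMF", "SCMF",
                                       "SWCMF"), ...) {
  variant <- match.arg(variant)
  preset <- switch(variant,
    MF    = list(regularizer_kind = "difference", weight_mode = "uniform",
                 max_shift_bins = 0L),
    CMF   = list(regularizer_kind = "damped_difference",
                 weight_mode = "uniform", max_shift_bins = 0L),
    WCMF  = list(regularizer_kind = "damped_difference",
                 weight_mode = "inverse_propensity", max_shift_bins = 0L),
    SCMF  = list(regularizer_kind = "damped_difference",
                 weight_mode = "uniform", max_shift_bins = 12L),
    SWCMF = list(regularizer_kind = "damped_difference",
                 weight_mode = "inverse_propensity", max_shift_bins = 12L))
  dots <- list(...)
  cfg <- do.call(factorization_config, utils::modifyList(preset, dots))
  cfg$variant <- variant
  cfg
}

replicate_flag <- function(boundary) {
  identical(match.arg(boundary, c("replicate", "zero")), "replicate")
}

# Extract (Y0, mask) from a state_matrix or a numeric matrix with NAs.
as_numeric_data <- function(m) {
  if (inherits(m, "state_matrix")) {
    Y <- m$values
    Y[!m$mask] <- 0
    list(Y = matrix(as.numeric(Y), nrow(Y), ncol(Y)), mask = m$mask)
  } else {
    Y <- as.matrix(m)
    mask <- !is.na(Y)
    Y[!mask] <- 0
    list(Y = Y, mask = mask)
  }
}

#' Penalized factorization objective
#'
#' The full discrepancy plus penalties:
#' `sum_n ||W_n . (Y_n - U_n V' Z_n)||^2 + b1 ||U||_F^2 + b2 ||V||_F^2 +
#' b3 ||R V||_F^2`. With all shifts zero this is the unshifted variational
#' objective. Weights multiply residuals before squaring; residuals at
#' shift-padded cells are taken against a latent value of 0.
#'
#' @param m a [state_matrix()] or numeric matrix with `NA` for missing.
#' @param W `N x T` weight matrix (zero off the mask).
#' @param model a fitted [fit_factor_model()] object, or a list with
#'   elements `U`, `V`, `shifts`, and `config`.
#' @return Non-negative scalar.
#' @export
objective_value <- function(m, W, model) {
  d <- as_numeric_data(m)
  cf <- model$config$reg_coefficients
  R <- model$regularizer
  if (is.null(R))
    R <- make_regularizer(model$config$regularizer_kind, ncol(d$Y),
                          gamma = model$config$gamma)
  L <- cpp_latent(model$U, model$V, as.integer(model$shifts),
                  replicate_flag(model$config$shift_boundary %||%
                                   "replicate"))
  sum((W * (d$Y - L))^2) + cf[1] * sum(model$U^2) +
    cf[2] * sum(model$V^2) + cf[3] * sum((R$matrix %*% model$V)^2)
}

#' Exact block update of the subject coefficients
#'
#' Solves, for each subject row, the weighted ridge problem
#' `min_u ||W_n . (Y_n - u V' Z_n)||^2 + b1 ||u||^2` in closed form.
#'
#' @param m data as in [objective_value()].
#' @param W weight matrix.
#' @param V `T x r` profile matrix.
#' @param shifts integer vector of per-row shifts (default all zero).
#' @param beta1 ridge coefficient (>= 0).
#' @param boundary shift boundary handling, as in
#'   [factorization_config()].
#' @return `N x r` coefficient matrix.
#' @export
update_coefficients <- function(m, W, V, shifts = NULL, beta1 = 1,
                                boundary = c("replicate", "zero")) {
  d <- as_numeric_data(m)
  if (is.null(shifts)) shifts <- integer(nrow(d$Y))
  cpp_update_U(d$Y, W^2, V, as.integer(shifts), beta1,
               replicate_flag(boundary))
}

#' Exact block update of the basic profiles
#'
#' Solves the stacked `(T r)`-dimensional quadratic subproblem for `V` at
#' fixed `U`, including weights, shifts and the temporal penalty
#' `b2 ||V||_F^2 + b3 ||R V||_F^2`, by one direct linear solve.
#'
#' @inheritParams update_coefficients
#' @param U `N x r` coefficient matrix.
#' @param beta2,beta3 penalty coefficients (>= 0).
#' @param regularizer a [make_regularizer()] operator.
#' @return `T x r` profile matrix.
#' @export
update_profiles <- function(m, W, U, shifts = NULL, beta2 = 1, beta3 = 1,
                            regularizer,
                            boundary = c("replicate", "zero")) {
  d <- as_numeric_data(m)
  if (is.null(shifts)) shifts <- integer(nrow(d$Y))
  RtR <- crossprod(regularizer$matrix)
  cpp_update_V(d$Y, W^2, U, as.integer(shifts), beta2, beta3, RtR,
               replicate_flag(boundary))
}

#' Exhaustive per-subject shift search
#'
#' For each row, finds the offset `z_n` in
#' `[-max_shift_bins, +max_shift_bins]` minimising the weighted
#' discrepancy of that row against the shifted profiles. Ties are broken
#' toward smaller `|z_n|`, then toward the negative shift. 12 bins equal
#' the 3-year bound used by the shifted variants.
#'
#' @inheritParams update_profiles
#' @param V `T x r` profile matrix.
#' @param max_shift_bins non-negative bound (<= 12).
#' @return Integer vector of length `N`.
#' @export
search_shifts <- function(m, W, U, V, max_shift_bins,
                          boundary = c("replicate", "zero")) {
  stopifnot(max_shift_bins >= 0, max_shift_bins <= 12)
  d <- as_numeric_data(m)
  as.integer(cpp_search_shifts(d$Y, W^2, U, V, as.integer(max_shift_bins),
                               replicate_flag(boundary)))
}

#' Maximum likelihood estimate of the observation reliability
#'
#' Under the Gaussian observation kernel with variance `1/(2 theta)`, the
#' MLE given a latent matrix is
#' `theta* = |Omega| / (2 sum_Omega (Y - M)^2)`.
#'
#' @param m a [state_matrix()] or numeric matrix with `NA` for missing.
#' @param latent latent matrix `M` of matching shape.
#' @return Positive scalar.
#' @export
mle_theta <- function(m, latent) {
  d <- as_numeric_data(m)
  if (!any(d$mask)) stop("no observed entries")
  rss <- sum((d$Y[d$mask] - latent[d$mask])^2)
  if (rss == 0)
    stop("degenerate fit: zero residual sum of squares, theta is unbounded")
  sum(d$mask) / (2 * rss)
}

#' Reconstruction error over unobserved entries
#'
#' `||P_{Omega^c}(M - Mhat)||_F^2 / (N T |Omega^c|bar)`, which reduces
#' algebraically to the mean squared error over the unobserved cells.
#'
#' @param truth,estimate `N x T` numeric matrices.
#' @param mask `N x T` logical matrix of *observed* cells.
#' @return Non-negative scalar.
#' @export
reconstruction_error <- function(truth, estimate, mask) {
  stopifnot(all(dim(truth) == dim(estimate)), all(dim(truth) == dim(mask)))
  unobs <- !mask
  if (!any(unobs)) stop("no unobserved entries to score")
  mean((truth[unobs] - estimate[unobs])^2)
}

#' Fit the factorization model
#'
#' Alternating block minimisation: exact coefficient update, exact profile
#' update, and (for shifted variants) an exhaustive shift search, each an
#' exact minimiser of its block, so the objective is non-increasing across
#' sweeps. Profiles are initialised `V[t, k] ~ N(0, 1)` and shifts at zero;
#' iterations stop when the relative Frobenius change of the latent matrix
#' between consecutive sweeps falls below `tol` (default 1e-6). After
#' convergence the observation reliability `theta` is set to its MLE.
#'
#' @param m a [state_matrix()], or a numeric matrix with `NA` marking
#'   unobserved cells.
#' @param config a [factorization_config()] or [variant_config()].
#' @param weights optional explicit `N x T` weight matrix; otherwise built
#'   from `config$weight_mode` (uniform weights for plain-matrix input).
#' @return An object of class `"factor_model"`: `U`, `V`, `shifts`,
#'   `theta`, `config`, `regularizer`, `weights`, `objective` (per-sweep
#'   trace), `converged`, `iterations`. The shift-adjusted latent matrix is
#'   available through [fitted()][fitted.factor_model()].
#' @export
fit_factor_model <- function(m, config = factorization_config(),
                             weights = NULL) {
  d <- as_numeric_data(m)
  N <- nrow(d$Y); Tn <- ncol(d$Y)
  if (!any(d$mask)) stop("need at least one observed entry")
  if (config$rank >= min(N, Tn))
    warning("rank ", config$rank, " is not small relative to min(N, T)")
  if (is.null(weights)) {
    weights <- if (inherits(m, "state_matrix"))
      build_weights(m, config$weight_mode)
    else matrix(as.numeric(d$mask), N, Tn)
  }
  if (any(weights[!d$mask] != 0) || any(weights[d$mask] <= 0))
    stop("weights must be positive exactly on the observed set")
  W2 <- weights^2
  cf <- config$reg_coefficients
  reg <- make_regularizer(config$regularizer_kind, Tn, gamma = config$gamma)
  RtR <- crossprod(reg$matrix)

  repl <- replicate_flag(config$shift_boundary %||% "replicate")
  set.seed(config$seed)
  V <- matrix(rnorm(Tn * config$rank), Tn, config$rank)
  z <- integer(N)
  obj <- numeric(0)
  M_prev <- NULL
  converged <- FALSE
  it <- 0L
  eps <- .Machine$double.eps
  for (it in seq_len(config$max_iter)) {
    U <- cpp_update_U(d$Y, W2, V, z, cf[1], repl)
    V <- cpp_update_V(d$Y, W2, U, z, cf[2], cf[3], RtR, repl)
    if (config$max_shift_bins > 0L)
      z <- as.integer(cpp_search_shifts(d$Y, W2, U, V,
                                        config$max_shift_bins, repl))
    M <- cpp_latent(U, V, z, repl)
    obj <- c(obj, sum(W2 * (d$Y - M)^2) + cf[1] * sum(U^2) +
               cf[2] * sum(V^2) + cf[3] * sum((reg$matrix %*% V)^2))
    if (!is.null(M_prev)) {
      rel <- norm(M - M_prev, "F") / max(norm(M_prev, "F"), eps)
      if (rel < config$tol) {
        converged <- TRUE
        break
      }
    }
    M_prev <- M
  }
  if (!converged)
    warning("factorization did not converge in ", config$max_iter,
            " sweeps (returning current estimate)")
  theta <- tryCatch(mle_theta(m, M), error = function(e) {
    warning("degenerate fit: zero residuals; setting theta = Inf")
    Inf
  })
  structure(list(U = U, V = V, shifts = z, theta = theta, config = config,
                 regularizer = reg, weights = weights, objective = obj,
                 converged = converged, iterations = it,
                 grid = if (inherits(m, "state_matrix")) m$grid
                        else time_grid(Tn)),
            class = "factor_model")
}

#' Shift-adjusted latent matrix of a fitted model
#'
#' Returns `Mhat` with row `n` equal to `U_n V' Z_n`, with bins left
#' uncovered by the shift filled according to the configured boundary
#' handling (edge replication by default).
#'
#' @param object a `"factor_model"`.
#' @param ... unused.
#' @return `N x T` numeric matrix.
#' @export
fitted.factor_model <- function(object, ...) {
  cpp_latent(object$U, object$V, as.integer(object$shifts),
             replicate_flag(object$config$shift_boundary %||% "replicate"))
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf(
    "<factor_model> %s rank %d, %d x %d, theta = %.3g, %d sweeps%s\n",
    x$config$variant %||% x$config$regularizer_kind, x$config$rank,
    nrow(x$U), nrow(x$V), x$theta, x$iterations,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
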