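#' Time grid for screening histories
#'
#' Screening results are discretised onto a regular grid of 3-month age
#' intervals. Column `t` (0-based bin index) covers ages
#' `[origin_age + t/4, origin_age + (t+1)/4)` years. Three months balances
#' temporal resolution against sparsity: healthy women are recalled every
#' 3 years, women at elevated risk every 3-6 months.
#'
#' @param n_bins number of columns `T` (>= 2).
#' @param bin_width_months width of one bin in months; fixed at 3.
#' @param origin_age age in years at the left edge of bin 0 (default 25, the
#'   recommended age of first screening).
#' @return An object of class `"time_grid"`.
#' @export
time_grid <- function(n_bins, bin_width_months = 3, origin_age = 25) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L)
    stop("`n_bins` must be an integer >= 2")
  if (bin_width_months != 3)
    stop("the time discretisation is fixed at 3-month bins")
  structure(
    list(n_bins = n_bins, bin_width_months = 3, origin_age = origin_age),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %d bins of 3 months, ages %.2f-%.2f\n",
              x$n_bins, x$origin_age, x$origin_age + x$n_bins / 4))
  invisible(x)
}

#' Partially observed state matrix
#'
#' The screening data are an `N x T` integer matrix `Y` whose observed
#' entries take values in `{1, 2, 3, 4}` (normal, low-risk, high-risk,
#' cancer, ordered by clinical severity). The set of observed cells is the
#' mask `Omega`; unobserved cells are ignored by all computations.
#'
#' @param values `N x T` numeric matrix; entries off the mask are arbitrary
#'   (stored as `NA`).
#' @param mask `N x T` logical matrix of observed cells.
#' @param grid a [time_grid()] with `n_bins == ncol(values)`.
#' @param subjects optional character vector of row labels.
#' @return An object of class `"state_matrix"` with elements `values`
#'   (integer matrix, `NA` off the mask), `mask`, `grid`, `subjects`.
#' @export
state_matrix <- function(values, mask, grid, subjects = NULL) {
  values <- as.matrix(values)
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!all(dim(values) == dim(mask)))
    stop("`values` and `mask` dimensions differ")
  if (nrow(values) < 1L) stop("need at least one subject row")
  if (grid$n_bins != ncol(values))
    stop("grid has ", grid$n_bins, " bins but matrix has ", ncol(values),
         " columns")
  obs <- values[mask]
  if (length(obs) && (anyNA(obs) || !all(obs %in% 1:4)))
    stop("observed states must lie in {1, 2, 3, 4}")
  v <- matrix(NA_integer_, nrow(values), ncol(values))
  v[mask] <- as.integer(values[mask])
  if (is.null(subjects)) subjects <- as.character(seq_len(nrow(values)))
  rownames(v) <- rownames(mask) <- subjects
  structure(list(values = v, mask = mask, grid = grid, subjects = subjects),
            class = "state_matrix")
}

#' @export
print.state_matrix <- function(x, ...) {
  cat(sprintf("<state_matrix> %d subjects x %d bins, density %.3f\n",
              nrow(x$values), ncol(x$values), density(x)))
  invisible(x)
}

#' @export
dim.state_matrix <- function(x) dim(x$values)

#' Load sparse screening histories from triplet records
#'
#' Materialises `(subject, bin, state)` triplets into a [state_matrix()].
#' Rows appear in order of first appearance of each subject key. When the
#' same `(subject, bin)` pair occurs more than once, the worst (maximum)
#' state is kept -- the conservative clinical choice.
#'
#' @param records data frame with columns `subject`, `bin`, `state`
#'   (0-based bin index, state in 1-4).
#' @param grid a [time_grid()].
#' @return A [state_matrix()].
#' @export
load_histories <- function(records, grid) {
  records <- as.data.frame(records)
  need <- c("subject", "bin", "state")
  if (!all(need %in% names(records)))
    stop("records need columns `subject`, `bin`, `state`")
  Tn <- grid$n_bins
  bad <- which(records$bin < 0 | records$bin >= Tn |
                 records$bin != floor(records$bin))
  if (length(bad))
    stop(sprintf("record %d (subject %s): bin %s outside [0, %d)",
                 bad[1], records$subject[bad[1]], records$bin[bad[1]], Tn))
  bad <- which(!(records$state %in% 1:4))
  if (length(bad))
    stop(sprintf("record %d (subject %s): state %s not in {1,2,3,4}",
                 bad[1], records$subject[bad[1]], records$state[bad[1]]))
  keys <- as.character(records$subject)
  subjects <- unique(keys)
  N <- max(length(subjects), 1L)
  v <- matrix(NA_integer_, N, Tn)
  if (nrow(records)) {
    i <- match(keys, subjects)
    j <- as.integer(records$bin) + 1L
    s <- as.integer(records$state)
    # keep the max state per (subject, bin)
    ord <- order(s)  # later (larger) writes win
    idx <- cbind(i, j)[ord, , drop = FALSE]
    v[idx] <- s[ord]
  } else {
    subjects <- "1"
  }
  state_matrix(v, !is.na(v), grid, subjects = subjects)
}

#' Convert a state matrix back to triplet records
#'
#' @param m a [state_matrix()].
#' @return data frame with columns `subject`, `bin`, `state`; one row per
#'   observed cell, subjects in row order, bins 0-based.
#' @export
as_records <- function(m) {
  stopifnot(inherits(m, "state_matrix"))
  idx <- which(t(m$mask))  # row-major so bins ascend within subject
  if (!length(idx))
    return(data.frame(subject = character(0), bin = integer(0),
                      state = integer(0)))
  Tn <- ncol(m$values)
  r <- (idx - 1L) %/% Tn + 1L
  b <- (idx - 1L) %% Tn
  data.frame(subject = m$subjects[r], bin = b,
             state = t(m$values)[idx], stringsAsFactors = FALSE)
}

#' Read screening histories from a delimited text file
#'
#' Expects header `subject,bin,state` (comma- or tab-separated); files
#' ending in `.gz` are decompressed transparently.
#'
#' @param path file path.
#' @param grid a [time_grid()]; if `NULL`, the grid spans
#'   `max(bin) + 1` bins.
#' @param sep field separator; `""` (default) auto-detects comma vs tab.
#' @return A [state_matrix()].
#' @export
read_histories <- function(path, grid = NULL, sep = "") {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  first <- readLines(con, n = 1L)
  close(con)
  if (sep == "") sep <- if (grepl("\t", first)) "\t" else ","
  rec <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (is.null(grid)) grid <- time_grid(max(rec$bin) + 1L)
  load_histories(rec, grid)
}

#' Write screening histories as triplet records
#'
#' Round-trips with [load_histories()] / [read_histories()]: reloading the
#' written records reproduces the matrix (up to row order).
#'
#' @param m a [state_matrix()].
#' @param path output file path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_histories <- function(m, path) {
  rec <- as_records(m)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.csv(rec, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fraction of observed entries
#'
#' The data density `|Omega| / (N T)`. Registry screening matrices run at
#' about 8% observed entries.
#'
#' @param x a [state_matrix()].
#' @param ... unused.
#' @return A fraction in `[0, 1]`.
#' @export
density.state_matrix <- function(x, ...) {
  mean(x$mask)
}
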