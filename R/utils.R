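# Internal helpers shared across modules.

# Mean Julian month, days. Fixed so the uneven-sampling time axis is
# continuous and site-independent.
DAYS_PER_MONTH <- 30.436875

#' Convert calendar dates to decimal months since the first sample
#'
#' The seasonality and time-decay analyses need a continuous time axis even
#' though sampling is roughly monthly and occasionally skips months. Dates
#' are mapped to days since the earliest date and divided by the mean Julian
#' month length (30.436875 days).
#'
#' @param dates a `Date` vector (or anything `as.Date()` accepts).
#' @param origin optional `Date` used as time zero; defaults to `min(dates)`.
#' @return numeric vector of decimal months, zero at `origin`.
#' @export
months_since <- function(dates, origin = NULL) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("unparseable dates: ", paste(which(is.na(dates)), collapse = ", "))
  if (is.null(origin)) origin <- min(dates)
  as.numeric(dates - as.Date(origin)) / DAYS_PER_MONTH
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state. Every exported stochastic operation funnels through this.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Derive a stream-specific 32-bit sub-seed so pipeline stages sharing one
# user seed do not reuse RNG streams.
sub_seed <- function(seed, stream) {
  (as.integer(seed) * 31L + as.integer(stream) * 7919L) %% 2147483647L
}

# Relative-abundance rows of a non-negative matrix; errors on empty samples.
rel_abund <- function(x) {
  tot <- rowSums(x)
  if (any(tot <= 0)) {
    stop("sample(s) with zero total: ", paste(rownames(x)[tot <= 0], collapse = ", "))
  }
  sweep(x, 1, tot, "/")
}

# Row-wise minima of a matrix, NA-free.
row_mins <- function(m) {
  if (ncol(m) == 1L) return(as.vector(m))
  do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

# all permutations of 1..n as a matrix (n! rows); guarded against blow-up.
all_permutations <- function(n) {
  if (n > 9) stop("exhaustive permutations limited to n <= 9 (", n, "! rows requested)")
  rec <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L, 1L))
    do.call(rbind, lapply(seq_along(v), function(i) cbind(v[i], rec(v[-i]))))
  }
  rec(seq_len(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
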