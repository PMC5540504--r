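# internal helpers shared across modules

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so generators never leak global state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Integer-sample shift with edge replication. Positive s moves content toward
# later time; vacated positions take the boundary value.
shift_vector <- function(x, s) {
  n <- length(x)
  s <- as.integer(s)
  if (abs(s) >= n) stop("shift magnitude must be smaller than the vector length",
                        call. = FALSE)
  if (s == 0L) return(x)
  if (s > 0L) c(rep(x[1L], s), x[seq_len(n - s)])
  else c(x[(-s + 1L):n], rep(x[n], -s))
}

# Uniform-grid check: relative spacing deviation against the median step.
check_uniform_grid <- function(time, tol = 1e-6, what = "time grid") {
  if (length(time) < 2L) stop(what, " must have at least two points", call. = FALSE)
  d <- diff(time)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1L] + 1L
    stop(what, " is not strictly increasing at row ", bad, call. = FALSE)
  }
  dt <- stats::median(d)
  if (max(abs(d - dt)) / dt > tol) {
    bad <- which.max(abs(d - dt)) + 1L
    stop(what, " spacing is non-uniform beyond tolerance at row ", bad,
         call. = FALSE)
  }
  dt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
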