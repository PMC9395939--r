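# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stop_config <- function(...) {
  stop(structure(
    class = c("dialogi_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    stop_config(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1,
                           open_lo = FALSE, open_hi = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (open_lo) x > lo else x >= lo) &&
    (if (open_hi) x < hi else x <= hi)
  if (!ok) {
    stop_config(sprintf("`%s` must lie in %s%g, %g%s", name,
                        if (open_lo) "(" else "[", lo, hi,
                        if (open_hi) ")" else "]"))
  }
  as.numeric(x)
}

# Row-wise L2 normalisation; zero rows stay zero.
normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nz <- nrm > 0
  m[nz, ] <- m[nz, , drop = FALSE] / nrm[nz]
  m
}

# Dense cosine-similarity matrix between rows of `m` (and optionally `m2`).
cosine_similarity <- function(m, m2 = NULL) {
  a <- normalize_rows(as.matrix(m))
  b <- if (is.null(m2)) a else normalize_rows(as.matrix(m2))
  tcrossprod(a, b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
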