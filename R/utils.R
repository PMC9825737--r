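# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible child seed from a master seed and a stream index.
# Linear congruential mix kept strictly below 2^31 so it is a valid R seed.
#' @noRd
child_seed <- function(master, i) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647
  s <- (abs(as.double(master)) %% m) + 1
  s <- (s * 48271) %% m
  s <- (s + as.double(i) * 16807) %% m
  as.integer(s)
}

# Evaluate `code` under `seed` without clobbering the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic 32-bit polynomial hash of an R object, used for
# params_fingerprint. Not cryptographic; only needs to be stable.
#' @noRd
params_fingerprint <- function(params) {
  s <- paste(deparse(params, control = c("keepNA", "keepInteger")), collapse = "")
  b <- utf8ToInt(s)
  h <- 2166136261
  for (x in b) {
    h <- (h * 31 + x) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' @noRd
is_count_vector <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(abs(x - round(x)) < tol)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
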