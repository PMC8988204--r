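# Internal helpers: classed errors, seed management, small samplers.

stop2 <- function(msg, class, call. = FALSE) {
  cnd <- structure(
    class = c(class, "cropmtl_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cnd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    stop2(sprintf("`%s` must be a single integer >= %d (got %s)",
                  name, min, paste(format(x), collapse = ", ")),
          "cropmtl_invalid_argument")
  }
  as.integer(x)
}

#' Run code with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded package functions never disturb the
#' user's random stream.
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation: folds integer components into a single
# 31-bit seed so per-record / per-stage streams are reproducible and
# order-independent. All arithmetic stays below 2^53 (exact in doubles).
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), vapply(list(...), as.numeric, numeric(1)))
  acc <- 0
  for (p in parts) acc <- (acc * 69069 + abs(p) + 1) %% 2147483629
  as.integer(acc + 1)
}

# Truncated normal on [-bound, bound] via rejection (vectorized; cheap when
# bound is ~3 sd as in the default target perturbation).
rtruncnorm <- function(n, sd = 1, bound = Inf) {
  if (sd == 0) return(rep(0, n))
  out <- rnorm(n, 0, sd)
  bad <- which(abs(out) > bound)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), 0, sd)
    bad <- bad[abs(out[bad]) > bound]
  }
  out
}
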