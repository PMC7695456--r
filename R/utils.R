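# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Derive an independent 32-bit sub-seed from a master seed and a stream index,
# so that e.g. adding neurons to the trace generator cannot perturb the trial
# sequence stream.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  x <- (abs(as.numeric(seed)) %% 2147483647) + 1
  for (ch in utf8ToInt(as.character(stream))) {
    x <- (x * 48271 + ch) %% 2147483647
  }
  as.integer(x %% 2147483646) + 1L
}

# Row-wise sample SD of a matrix without extra dependencies.
row_sds <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  sqrt(pmax(rowSums((x - m)^2), 0) / (n - 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)
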