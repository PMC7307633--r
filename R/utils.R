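# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.euclid <- function(p, q) sqrt(sum((p - q)^2))

# trapezoidal integral of y over x
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is left untouched. seed = NULL runs in the ambient stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# Deterministic per-stage seed derived from a run seed. Offsets keep the
# stage streams distinct; result stays inside 32-bit integer range.
.stage_seed <- function(seed, stage) {
  offsets <- c(morpho = 101L, ca = 211L, ephys = 307L, model = 401L,
               neuropil = 503L)
  off <- offsets[[stage]] %||% 997L
  (as.integer(seed) * 1009L + off) %% 2147483629L
}

.assert_scalar_num <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  bad <- if (strict) x <= min else x < min
  if (bad)
    stop(sprintf("`%s` must be %s %s", name, if (strict) ">" else ">=", min),
         call. = FALSE)
  invisible(x)
}
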