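#' @keywords internal
#' @useDynLib nadhtr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Rec. 601 luma; the scale the background cutoff and optical density work on.
.luminance <- function(px) {
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

.is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)

.assert <- function(ok, ...) if (!isTRUE(ok)) stop(..., call. = FALSE)
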