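# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  Every exported function that consumes
# randomness routes it through here so that results are reproducible and the
# user's RNG stream is left untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Pearson correlation of two vectors; NA if either has zero variance.
pearson <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) return(NA_real_)
  stats::cor(a, b)
}

# Row-wise L2 normalisation; zero rows are an error for the callers that use it.
unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("zero-norm row encountered")
  m / nrm
}

# Cosine-similarity matrix between the rows of a and the rows of b.
cosine_sim <- function(a, b) {
  unit_rows(a) %*% t(unit_rows(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min)
    stop(sprintf("'%s' must be a finite scalar >= %s", name, format(min)))
  invisible(x)
}
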