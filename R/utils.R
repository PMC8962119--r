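# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive child seeds deterministically from a root seed
#'
#' All stochastic stages of the pipeline draw their seeds from a single root
#' seed through this function, so a whole run is reproducible from one
#' integer.  Child seeds stay below 2^31 - 1.
#'
#' @param root integer root seed.
#' @param n number of child seeds to derive.
#' @return integer vector of `n` seeds.
#' @export
split_seed <- function(root, n) {
  stopifnot(is.numeric(root), length(root) == 1L, n >= 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(root))
  sample.int(.Machine$integer.max - 1L, n)
}

# run expr with a local RNG state seeded by `seed`; restores caller state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Cholesky with jitter escalation (1e-10 -> 1e-6) for near-singular matrices
chol_jitter <- function(M, label = "V") {
  ans <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(ans)) return(ans)
  for (j in c(1e-10, 1e-8, 1e-6)) {
    ans <- tryCatch(chol(M + diag(j * mean(diag(M)), nrow(M))),
                    error = function(e) NULL)
    if (!is.null(ans)) return(ans)
  }
  stop(sprintf("matrix %s is not positive definite (jitter up to 1e-6 failed)",
               label))
}
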