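#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so generators are pure functions of their arguments.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Derive independent sub-seeds from a master seed
#' @keywords internal
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
}

# Largest-remainder (Hamilton) apportionment of n among proportions p.
# Ties on fractional remainder are broken by position order.
largest_remainder <- function(n, p) {
  if (any(p < 0)) stop("proportions must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9) stop("proportions must sum to 1", call. = FALSE)
  q <- n * p
  base <- floor(q + 1e-12)
  left <- n - sum(base)
  if (left > 0) {
    frac <- q - base
    ord <- order(-frac, seq_along(p))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}
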