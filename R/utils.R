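# Internal numerical helpers.

#' @keywords internal
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix, tolerant of -Inf entries.
#' @keywords internal
row_logsumexp <- function(x) {
  m <- do.call(pmax, c(as.data.frame(x), na.rm = TRUE))
  out <- m + log(rowSums(exp(x - m)))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

# Run an expression with a locally fixed RNG seed, restoring the caller's
# RNG state afterwards. All exported generators funnel through this so a
# (config, seed) pair is fully reproducible.
#' @keywords internal
with_seed <- function(seed, expr) {
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
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
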