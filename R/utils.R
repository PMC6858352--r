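# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds R's RNG with `seed`, runs `expr`, and restores the caller's RNG
#' state afterwards, so library code never clobbers user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  expr
}

# Mix a base seed with an index into a 32-bit-safe derived seed.
derive_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) * 1000003 + as.numeric(index)) %% 2147483647)
}

# Summed-area table with a zero top/left guard row, so that the sum of
# m[r1:r2, c1:c2] is S[r2+1,c2+1] - S[r1,c2+1] - S[r2+1,c1] + S[r1,c1].
integral_image <- function(m) {
  S <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  cs <- apply(m, 2L, cumsum)            # cumulative down rows
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)
  S[-1L, -1L] <- t(apply(cs, 1L, cumsum))  # then across columns
  S
}

# Sum of every w x w window of m at positions stepped by `step`,
# top-left rows `rows0`/cols `cols0` (0-based). Returns a matrix
# length(rows0) x length(cols0).
box_sums <- function(m, w, rows0, cols0) {
  S <- integral_image(m)
  r1 <- rows0 + 1L
  c1 <- cols0 + 1L
  r2 <- rows0 + w
  c2 <- cols0 + w
  S[r2 + 1L, c2 + 1L, drop = FALSE] -
    S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] +
    S[r1, c1, drop = FALSE]
}

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "duvmap_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x)
}
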