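# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` under a fixed RNG seed, restoring the caller's RNG state on exit.
# All stochastic entry points funnel their seed through this so that library
# calls never clobber the user's random stream.
with_preserved_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used here to compare recovered clusters against planted class labels.
#' 1 means identical partitions (up to relabeling), 0 is the expected
#' agreement of independent random partitions.
#'
#' @param a,b vectors of equal length; any label type coercible to factor.
#' @return a single number in \[-1, 1\].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  if (length(a) == 0L) stop("empty labelings")
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  max_index <- (si + sj) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sij - expected) / (max_index - expected)
}

# floor-truncate to `digits` decimals, guarding against binary representation
# artefacts (e.g. 6.72 stored as 6.71999...).
trunc_digits <- function(x, digits = 2L) {
  scale <- 10^digits
  trunc(x * scale + sign(x) * 1e-9) / scale
}
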