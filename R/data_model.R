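# Core containers: athlete cohorts (n x d score tables) and partitions.

#' Default anxiety factor names
#'
#' The twelve stress factors grouped in three blocks of four: A1--A4
#' (physical condition), B1--B4 (competition state), C1--C4 (cognitive
#' state).
#'
#' @return character vector of length 12.
#' @export
default_factors <- function() {
  c(paste0("A", 1:4), paste0("B", 1:4), paste0("C", 1:4))
}

#' Construct an athlete cohort
#'
#' A cohort is an n x d table of numeric factor scores, one row per athlete,
#' with unique athlete ids and named factor columns. Scores are nominally on
#' a \[0, 10\] scale but the container does not enforce the range (see
#' [validate_scores()]).
#'
#' @param scores numeric matrix or data frame, athletes in rows.
#' @param ids character vector of unique athlete labels; defaults to the
#'   row names of `scores`, then to `S1..Sn`.
#' @param factor_names column labels; defaults to existing column names,
#'   then to [default_factors()] when d = 12, then to `F1..Fd`.
#' @return an object of class `cohort` with elements `scores` (named numeric
#'   matrix), `ids`, and `factor_names`.
#' @export
#' @examples
#' x <- cohort(matrix(runif(24, 0, 10), 2, 12))
#' dim(x$scores)
cohort <- function(scores, ids = NULL, factor_names = NULL) {
  scores <- as.matrix(scores)
  if (!is.numeric(scores)) stop("scores must be numeric")
  n <- nrow(scores)
  d <- ncol(scores)
  if (n == 0L || d == 0L) stop("empty dataset")
  if (any(!is.finite(scores))) stop("all scores must be finite")
  ids <- as.character(ids %||% rownames(scores) %||% paste0("S", seq_len(n)))
  if (length(ids) != n) stop("ids length must match number of rows")
  if (anyDuplicated(ids)) {
    stop("duplicate athlete ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  factor_names <- as.character(
    factor_names %||% colnames(scores) %||%
      (if (d == 12L) default_factors() else paste0("F", seq_len(d)))
  )
  if (length(factor_names) != d) stop("factor_names length must match number of columns")
  dimnames(scores) <- list(ids, factor_names)
  structure(list(scores = scores, ids = ids, factor_names = factor_names),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d athletes x %d factors\n", nrow(x$scores), ncol(x$scores)))
  cat("factors:", paste(x$factor_names, collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.cohort <- function(x, ...) {
  data.frame(id = x$ids, x$scores, row.names = NULL, check.names = FALSE)
}

# accept a cohort or a bare numeric matrix wherever scores are needed
as_score_matrix <- function(x) {
  if (inherits(x, "cohort")) return(x$scores)
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("expected a cohort or numeric matrix")
  m
}

#' Read a cohort from CSV
#'
#' Expects a header row, a first column of unique athlete ids, and one
#' numeric column per factor (comma separated, decimal point, UTF-8).
#'
#' @param path CSV file path.
#' @return a [cohort()].
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty dataset: ", path)
  if (ncol(df) < 2L) stop("need an id column plus at least one score column: ", path)
  ids <- df[[1L]]
  num <- df[, -1L, drop = FALSE]
  parsed <- suppressWarnings(vapply(num, as.numeric, numeric(nrow(df))))
  parsed <- matrix(parsed, nrow = nrow(df),
                   dimnames = list(NULL, colnames(num)))
  if (any(is.na(parsed))) {
    bad <- which(is.na(parsed), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric score at row %d, column '%s'",
                 bad[1L], colnames(num)[bad[2L]]))
  }
  cohort(parsed, ids = ids, factor_names = colnames(num))
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: first column `id`, one column per factor.
#'
#' @param x a [cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' List scores outside an allowed range
#'
#' Scores are nominally standardized to \[0, 10\]; values outside the range
#' are reported rather than rejected because neither the clustering nor the
#' classifier requires bounded inputs.
#'
#' @param x a [cohort()].
#' @param lo,hi range bounds, `lo < hi`.
#' @return data frame with columns `id`, `factor`, `value`; zero rows iff
#'   every score lies in `[lo, hi]`.
#' @export
validate_scores <- function(x, lo = 0, hi = 10) {
  stopifnot(inherits(x, "cohort"))
  if (!(lo < hi)) stop("degenerate range: lo must be < hi")
  bad <- which(x$scores < lo | x$scores > hi, arr.ind = TRUE)
  data.frame(id = x$ids[bad[, 1L]],
             factor = x$factor_names[bad[, 2L]],
             value = x$scores[bad],
             row.names = NULL)
}

#' Construct a partition of a cohort
#'
#' A partition is a set of pairwise-disjoint, non-empty clusters of athlete
#' ids whose union covers the cohort exactly. Invariants are checked at
#' construction.
#'
#' @param clusters list of character vectors of athlete ids.
#' @param ids the full id universe the clusters must cover.
#' @return an object of class `stress_partition` with elements `clusters`
#'   and `ids`.
#' @export
partition <- function(clusters, ids) {
  ids <- as.character(ids)
  clusters <- lapply(clusters, as.character)
  if (any(lengths(clusters) == 0L)) stop("empty cluster in partition")
  flat <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(flat)) stop("clusters are not disjoint")
  if (!setequal(flat, ids) || length(flat) != length(ids)) {
    stop("clusters do not cover the id universe exactly")
  }
  structure(list(clusters = clusters, ids = ids), class = "stress_partition")
}

#' @export
print.stress_partition <- function(x, ...) {
  cat(sprintf("<partition> %d clusters over %d athletes (sizes: %s)\n",
              length(x$clusters), length(x$ids),
              paste(lengths(x$clusters), collapse = ", ")))
  invisible(x)
}

#' Cluster labels of a partition
#'
#' @param p a [partition()].
#' @return named integer vector: for each id (in the cohort's original
#'   order) the 1-based index of its cluster.
#' @export
partition_labels <- function(p) {
  stopifnot(inherits(p, "stress_partition"))
  lab <- integer(length(p$ids))
  names(lab) <- p$ids
  for (k in seq_along(p$clusters)) lab[p$clusters[[k]]] <- k
  lab
}

#' Write a partition as a two-column CSV (id, cluster)
#'
#' @param p a [partition()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(p, path) {
  lab <- partition_labels(p)
  utils::write.csv(data.frame(id = names(lab), cluster = unname(lab)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
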