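# Weighted stress scoring, per-factor cohort summaries, and factor grouping
# by a dendrogram cut on correlation distance.

#' Weighted stress-identification score Q
#'
#' `Q = sum(w_i e_i) / sum(w_i)`: the weight-normalized mean of per-factor
#' scores. Invariant under uniform rescaling of the weights and bounded by
#' the range of the scores; equals the arithmetic mean under uniform
#' weights.
#'
#' @param e numeric factor scores.
#' @param w non-negative weights, not all zero; defaults to uniform.
#' @return a single number in `[min(e), max(e)]`.
#' @export
#' @examples
#' weighted_score(c(2, 4, 6))            # 4
#' weighted_score(c(7, 1, 9), c(1, 0, 0))  # 7
weighted_score <- function(e, w = rep(1, length(e))) {
  if (length(e) != length(w)) stop("scores and weights must have equal length")
  if (length(e) == 0L) stop("empty score vector")
  if (any(w < 0)) stop("weights must be non-negative")
  sw <- sum(w)
  if (sw <= 0) stop("weights must not all be zero")
  sum(w * e) / sw
}

#' Per-factor column averages of a cohort
#'
#' Arithmetic mean of each factor column. By default the means are
#' floor-truncated (not rounded) to two decimals, the convention used in
#' published score tables of this kind (e.g. a column mean of 6.477 prints
#' as 6.47).
#'
#' @param x a [cohort()].
#' @param digits decimals kept by truncation.
#' @param truncate set FALSE for the exact means.
#' @return named numeric vector, one entry per factor.
#' @export
column_summary <- function(x, digits = 2L, truncate = TRUE) {
  stopifnot(inherits(x, "cohort"))
  m <- colMeans(x$scores)
  if (truncate) m <- trunc_digits(m, digits)
  m
}

#' Group factors by cutting a correlation dendrogram
#'
#' Factor columns are clustered by average-linkage agglomeration under
#' correlation distance `1 - Pearson r` and the dendrogram is cut at the
#' given height (default 0.90): merges at height <= `cut` are kept. Factors
#' that co-vary across athletes -- e.g. the four physical-condition factors
#' -- fall into one group. Zero-variance columns have no defined
#' correlation and are isolated as singletons with a warning.
#'
#' @param x a [cohort()] with at least 2 factors and 3 athletes.
#' @param cut dendrogram cut height on the `1 - r` scale.
#' @return named list of character vectors partitioning the factor names;
#'   the merge heights are attached as attribute `heights`.
#' @export
factor_grouping <- function(x, cut = 0.90) {
  stopifnot(inherits(x, "cohort"))
  scores <- x$scores
  if (ncol(scores) < 2L) stop("need at least 2 factors")
  if (nrow(scores) < 3L) stop("need at least 3 athletes")
  sds <- apply(scores, 2L, stats::sd)
  constant <- x$factor_names[sds == 0]
  live <- x$factor_names[sds > 0]
  if (length(constant) > 0L) {
    warning("zero-variance factor(s) isolated as singletons: ",
            paste(constant, collapse = ", "))
  }
  groups <- list()
  heights <- numeric(0)
  if (length(live) >= 2L) {
    dmat <- 1 - stats::cor(scores[, live, drop = FALSE])
    hc <- stats::hclust(stats::as.dist(dmat), method = "average")
    heights <- hc$height
    memb <- stats::cutree(hc, h = cut)
    groups <- split(live, memb)
  } else if (length(live) == 1L) {
    groups <- list(live)
  }
  groups <- c(unname(groups), as.list(constant))
  names(groups) <- paste0("G", seq_along(groups))
  attr(groups, "heights") <- heights
  groups
}

#' Class proportions of a set of anxiety assignments
#'
#' @param assignments character/factor vector of anxiety classes, one per
#'   athlete.
#' @param classes class universe to report (zero counts included).
#' @return named numeric vector of percentages summing to 100.
#' @export
#' @examples
#' class_proportions(c("physical", "physical", "competition"))
class_proportions <- function(assignments,
                              classes = names(default_class_codes())) {
  if (length(assignments) == 0L) stop("empty assignment vector")
  assignments <- as.character(assignments)
  classes <- union(classes, unique(assignments))
  counts <- table(factor(assignments, levels = classes))
  pct <- 100 * as.numeric(counts) / length(assignments)
  names(pct) <- classes
  pct
}
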