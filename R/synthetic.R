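# Synthetic athlete-cohort generator and embedded worked-example fixtures.
#
# The generator emulates the structure the real (undeposited) training
# cohort is described to have: 12 factor scores on [0,10] in three blocks of
# four (A physical, B competition, C cognitive), three anxiety classes each
# elevating its own block, and a 500-athlete default with a 30/40/30
# physical/competition/cognitive split.

#' Generator configuration for synthetic cohorts
#'
#' @param n cohort size (default 500, the size of the cohort the method was
#'   originally trained on).
#' @param proportions named class fractions summing to 1; default
#'   physical 0.30, competition 0.40, cognitive 0.30 -- the only class
#'   split documented for this kind of cohort.
#' @param elevated_mean mean score of the four factors in an athlete's own
#'   anxiety block (default 7.5).
#' @param baseline_mean mean score of the remaining eight factors
#'   (default 4.5).
#' @param spread per-factor Gaussian noise sd (default 1.0).
#' @param seed RNG seed; generation is byte-reproducible per seed.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n = 500L,
                             proportions = c(physical = 0.30,
                                             competition = 0.40,
                                             cognitive = 0.30),
                             elevated_mean = 7.5, baseline_mean = 4.5,
                             spread = 1.0, seed = 1L) {
  n <- as.integer(n)
  if (n < 0L) stop("n must be >= 0")
  if (!setequal(names(proportions), c("physical", "competition", "cognitive"))) {
    stop("proportions must be named physical/competition/cognitive")
  }
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  if (any(proportions < 0)) stop("proportions must be non-negative")
  if (elevated_mean < 0 || elevated_mean > 10 ||
      baseline_mean < 0 || baseline_mean > 10) {
    stop("block means must lie in [0, 10]")
  }
  if (spread <= 0) stop("spread must be positive")
  structure(list(n = n, proportions = proportions,
                 elevated_mean = elevated_mean, baseline_mean = baseline_mean,
                 spread = spread, seed = as.integer(seed)),
            class = "generator_config")
}

# factor-block columns per anxiety class (A = 1:4, B = 5:8, C = 9:12)
class_block_columns <- function() {
  list(physical = 1:4, competition = 5:8, cognitive = 9:12)
}

#' Generate a synthetic athlete cohort with planted anxiety classes
#'
#' Each athlete of class k draws its four in-block factor scores from
#' `Normal(elevated_mean, spread)` and the other eight from
#' `Normal(baseline_mean, spread)`; all scores are clipped to \[0, 10\].
#' Class counts are `round(n * proportions)` (any rounding remainder is
#' absorbed by the largest class). Athletes are ordered physical, then
#' competition, then cognitive.
#'
#' @param config a [generator_config()].
#' @return list with `cohort` (a [cohort()] with factors A1..C4) and
#'   `labels` (named character vector of anxiety classes).
#' @export
#' @examples
#' g <- generate_cohort(generator_config(n = 30, seed = 7))
#' table(g$labels)
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n
  order3 <- c("physical", "competition", "cognitive")
  counts <- round(n * config$proportions[order3])
  excess <- n - sum(counts)
  if (excess != 0L) {
    big <- which.max(counts)
    counts[big] <- counts[big] + excess
  }
  labels <- rep(order3, times = counts)
  if (n == 0L) {
    return(list(cohort = NULL, labels = character(0)))
  }
  blocks <- class_block_columns()
  scores <- with_preserved_seed(config$seed, {
    m <- matrix(stats::rnorm(n * 12L, config$baseline_mean, config$spread),
                nrow = n, ncol = 12L)
    for (cls in order3) {
      rows <- which(labels == cls)
      cols <- blocks[[cls]]
      m[rows, cols] <- stats::rnorm(length(rows) * length(cols),
                                    config$elevated_mean, config$spread)
    }
    m
  })
  scores <- pmin(pmax(scores, 0), 10)
  ids <- sprintf("S%0*d", nchar(n), seq_len(n))
  names(labels) <- ids
  list(cohort = cohort(scores, ids = ids, factor_names = default_factors()),
       labels = labels)
}

#' Worked-example score table: ten athletes, twelve factors
#'
#' The published 10 x 12 table of standardized psychological pressure
#' scores (athletes M1--M10) used throughout the tests. Column order is as
#' printed (A1, B1, C1, A2, ...). The source table labels its last row
#' "M1" -- an evident duplicate; it is stored as M10, consistent with the
#' companion class-assignment table.
#'
#' @return a [cohort()] with 10 athletes and 12 factors.
#' @export
#' @examples
#' table3_fixture()$scores["M1", "A1"]  # 7.44
table3_fixture <- function() {
  vals <- c(
    7.44, 4.56, 4.48, 7.98, 3.45, 7.89, 8.29, 4.55, 3.72, 7.31, 5.61, 8.56,
    3.15, 7.38, 7.26, 5.01, 6.38, 5.06, 3.16, 8.26, 8.08, 4.61, 5.46, 7.38,
    4.61, 3.80, 3.86, 8.93, 3.60, 8.43, 6.63, 5.90, 6.10, 6.53, 6.53, 3.80,
    7.05, 4.55, 8.78, 4.44, 4.43, 6.61, 7.84, 7.34, 5.88, 4.92, 8.81, 8.55,
    3.19, 4.94, 3.15, 6.27, 7.07, 5.65, 3.13, 8.98, 8.36, 6.53, 7.68, 4.94,
    8.42, 8.29, 4.55, 3.72, 7.31, 5.61, 4.56, 4.48, 7.98, 3.45, 7.89, 8.29,
    8.05, 3.16, 8.26, 8.08, 4.61, 5.46, 7.38, 7.26, 5.01, 6.38, 5.06, 8.16,
    8.68, 6.63, 5.90, 6.10, 6.53, 6.53, 3.80, 3.86, 8.93, 3.60, 8.43, 6.63,
    8.77, 7.84, 7.34, 5.88, 4.92, 8.81, 4.55, 8.78, 4.44, 4.43, 6.61, 7.84,
    7.87, 3.13, 8.98, 8.36, 6.53, 7.68, 4.94, 3.15, 6.27, 7.07, 5.65, 8.13)
  m <- matrix(vals, nrow = 10, byrow = TRUE)
  cohort(m, ids = paste0("M", 1:10),
         factor_names = c("A1", "B1", "C1", "A2", "B2", "C2",
                          "A3", "B3", "C3", "A4", "B4", "C4"))
}

#' Worked-example anxiety assignments for the ten athletes
#'
#' The published model-vs-manual class assignments for athletes M1--M10.
#' The two columns agree on nine of the ten athletes; only M10 differs
#' (model: competition, manual: cognitive).
#'
#' @return list with named character vectors `rbf` and `manual`.
#' @export
table4_fixture <- function() {
  ids <- paste0("M", 1:10)
  rbf <- c("competition", "competition", "physical", "cognitive",
           "competition", "cognitive", "physical", "physical",
           "competition", "competition")
  manual <- c("competition", "competition", "physical", "cognitive",
              "competition", "cognitive", "physical", "physical",
              "competition", "cognitive")
  names(rbf) <- ids
  names(manual) <- ids
  list(rbf = rbf, manual = manual)
}
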