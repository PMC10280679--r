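# Two-phase hierarchical clustering: a top-down dividing phase that splits
# the cohort at histogram valleys until no valid split remains, then a
# bottom-up agglomerating phase that re-merges sibling subclasses, deepest
# splits first.

#' Clustering configuration
#'
#' @param bins number of equal-width histogram bins per dimension (>= 2).
#' @param min_cluster_size classes smaller than `2 * min_cluster_size` are
#'   never split, and no subclass smaller than this is ever produced.
#' @param smoothing_window odd moving-average window applied to bin counts
#'   before valley detection; 1 disables smoothing.
#' @param seed reserved; the dividing/agglomerating core is deterministic.
#' @return a list of class `clus_config`.
#' @export
clus_config <- function(bins = 16L, min_cluster_size = 2L,
                        smoothing_window = 3L, seed = 1L) {
  bins <- as.integer(bins)
  min_cluster_size <- as.integer(min_cluster_size)
  smoothing_window <- as.integer(smoothing_window)
  if (bins < 2L) stop("bins must be >= 2")
  if (min_cluster_size < 1L) stop("min_cluster_size must be >= 1")
  if (smoothing_window < 1L || smoothing_window %% 2L == 0L) {
    stop("smoothing_window must be a positive odd integer")
  }
  structure(list(bins = bins, min_cluster_size = min_cluster_size,
                 smoothing_window = smoothing_window, seed = as.integer(seed)),
            class = "clus_config")
}

#' Per-dimension histogram of a class
#'
#' Equal-width bins over the class's own `[min, max]` range in one
#' dimension. Interior bins are left-closed; the last bin is right-closed so
#' the maximum is always counted. When every value is identical the
#' histogram degenerates to a single occupied bin and is flagged.
#'
#' @param x numeric vector: the class's values in one dimension, or a
#'   [cohort()] together with `dim`.
#' @param bins number of bins B (>= 2).
#' @param dim 1-based dimension index, required when `x` is a cohort.
#' @return list with `edges` (B+1 boundaries), `counts` (B integers summing
#'   to `length(x)`), `medians` (per-bin median value, NA for empty bins),
#'   and `degenerate` (TRUE iff all values equal).
#' @export
#' @examples
#' h <- build_histogram(c(1, 1, 2, 9, 9), bins = 2)
#' h$counts  # 3 2
build_histogram <- function(x, bins, dim = NULL) {
  if (inherits(x, "cohort") || is.matrix(x)) {
    if (is.null(dim)) stop("dim is required when x is a cohort or matrix")
    x <- as_score_matrix(x)[, dim]
  }
  bins <- as.integer(bins)
  if (length(x) == 0L) stop("class is empty")
  if (bins < 2L) stop("bins must be >= 2")
  lo <- min(x)
  hi <- max(x)
  if (lo == hi) {
    counts <- c(length(x), rep(0L, bins - 1L))
    meds <- c(lo, rep(NA_real_, bins - 1L))
    return(list(edges = seq(lo, lo + 1, length.out = bins + 1L),
                counts = counts, medians = meds, degenerate = TRUE))
  }
  width <- (hi - lo) / bins
  idx <- pmin(floor((x - lo) / width) + 1L, bins)
  counts <- tabulate(idx, nbins = bins)
  meds <- rep(NA_real_, bins)
  occ <- sort(unique(idx))
  meds[occ] <- vapply(occ, function(b) stats::median(x[idx == b]), numeric(1))
  list(edges = seq(lo, hi, length.out = bins + 1L), counts = counts,
       medians = meds, degenerate = FALSE)
}

# centered moving average with window w (odd); shrinks at the edges
smooth_counts <- function(counts, w) {
  if (w <= 1L) return(as.numeric(counts))
  k <- (w - 1L) %/% 2L
  B <- length(counts)
  vapply(seq_len(B), function(j) {
    mean(counts[max(1L, j - k):min(B, j + k)])
  }, numeric(1))
}

# valley bins: interior local minima of the smoothed counts (weak minima,
# strictly below at least one neighbour, so flat stretches do not qualify)
valley_bins <- function(s) {
  B <- length(s)
  if (B < 3L) return(integer(0))
  j <- 2:(B - 1L)
  j[s[j] <= s[j - 1L] & s[j] <= s[j + 1L] & (s[j] < s[j - 1L] | s[j] < s[j + 1L])]
}

#' Find the best valid split position of a class
#'
#' Scans every dimension's histogram for valley bins: interior local minima
#' of the smoothed counts whose smoothed count also dips significantly below
#' the class's mean per-bin count -- below `n/B - 2*sqrt(n/B)`, i.e. about
#' two Poisson standard deviations, so that noise dips in flat or unimodal
#' histograms do not qualify. A candidate split `(dim, h)` -- where `h` is the
#' median value inside the valley bin, or the bin midpoint when the bin is
#' empty -- is valid iff, after cutting the class into `{<= h}` and `{> h}`,
#' both subclasses (a) have at least `min_cluster_size` members and (b)
#' contain a genuine mode of the parent's distribution: under the parent's
#' binning of that dimension, each subclass's maximum per-bin count must be
#' strictly greater than the parent's mean per-bin count `n / bins`. Among
#' valid candidates the deepest valley wins; ties break to the lowest
#' dimension index, then the lowest bin index.
#'
#' @param x a [cohort()] or numeric score matrix (the class members).
#' @param config a [clus_config()].
#' @return `NULL` when no valid split exists (a normal outcome), otherwise a
#'   list of class `split_position` with `dim`, `threshold`, `bin`, `depth`.
#' @export
find_split <- function(x, config = clus_config()) {
  scores <- as_score_matrix(x)
  n <- nrow(scores)
  # effective bin count scales with class size: a sparse histogram (mean
  # count n/B near 1) fabricates valleys out of sampling noise
  B <- min(config$bins, as.integer(ceiling(sqrt(n))))
  if (B < 2L) return(NULL)
  if (n < 2L * config$min_cluster_size) return(NULL)
  best <- NULL
  for (i in seq_len(ncol(scores))) {
    v <- scores[, i]
    if (min(v) == max(v)) next
    h <- build_histogram(v, B)
    s <- smooth_counts(h$counts, config$smoothing_window)
    mean_count <- n / B
    # a genuine valley dips significantly below the mean bin count; under a
    # roughly Poisson(n/B) null for a structureless bin, 2 sd below the
    # mean rejects noise dips in flat or unimodal histograms
    valley_cut <- mean_count - 2 * sqrt(mean_count)
    for (b in valley_bins(s)) {
      if (s[b] >= valley_cut) next
      thr <- h$medians[b]
      if (is.na(thr)) thr <- (h$edges[b] + h$edges[b + 1L]) / 2
      left <- v <= thr
      n1 <- sum(left)
      n2 <- n - n1
      if (n1 < config$min_cluster_size || n2 < config$min_cluster_size) next
      if (!split_is_valid(v[left], v[!left], n, B, h$edges,
                          config$smoothing_window)) next
      depth <- min(max(s[1:(b - 1L)]), max(s[(b + 1L):B])) - s[b]
      if (depth <= 0) next  # plateau, not a valley
      if (is.null(best) || depth > best$depth) {
        best <- list(dim = i, threshold = thr, bin = b, depth = depth)
      }
      # ties keep the earlier (lower dim, lower bin) candidate by loop order
    }
  }
  if (!is.null(best)) class(best) <- "split_position"
  best
}

# bin counts of values under a fixed (parent) binning
counts_under_edges <- function(x, edges) {
  B <- length(edges) - 1L
  width <- (edges[B + 1L] - edges[1L]) / B
  idx <- pmin(pmax(floor((x - edges[1L]) / width) + 1L, 1L), B)
  tabulate(idx, nbins = B)
}

# the split-validity condition: under the parent's binning of the split
# dimension, each subclass's maximum (smoothed) per-bin count must exceed
# the parent's mean per-bin count n / B -- i.e. both sides of the valley
# contain a genuine mode of the parent's distribution
split_is_valid <- function(v1, v2, parent_n, B, edges, window) {
  threshold <- parent_n / B
  max(smooth_counts(counts_under_edges(v1, edges), window)) > threshold &&
    max(smooth_counts(counts_under_edges(v2, edges), window)) > threshold
}

#' Cut a class in two at a split position
#'
#' Members with value `<= h` in the split dimension go left, the rest right
#' (the threshold itself is inclusive on the left).
#'
#' @param x a [cohort()] or score matrix (the class members).
#' @param pos a `split_position` from [find_split()], or any list with
#'   `dim` and `threshold`.
#' @return list with integer row indices `left` and `right`, both non-empty.
#' @export
split_class <- function(x, pos) {
  scores <- as_score_matrix(x)
  v <- scores[, pos$dim]
  left <- which(v <= pos$threshold)
  right <- which(v > pos$threshold)
  if (length(left) == 0L || length(right) == 0L) {
    stop("empty subclass: threshold ", pos$threshold,
         " does not separate dimension ", pos$dim)
  }
  list(left = left, right = right)
}

#' Dividing phase: recursively split the cohort at histogram valleys
#'
#' Starts from the whole cohort as the root class (level 1) and repeatedly
#' applies [find_split()]/[split_class()] to every splittable leaf, placing
#' children at the parent's level + 1, until no leaf admits a valid split.
#' The goal is deliberate over-segmentation: the leaves are at least as
#' numerous as the true clusters, and the agglomerating phase merges
#' siblings back together.
#'
#' @param x a [cohort()].
#' @param config a [clus_config()].
#' @return an object of class `cluster_tree`: a flat list of nodes (each
#'   with `members` as row indices, `level`, `parent`, `children`, `split`,
#'   and a display `tag`), plus the cohort ids and the deepest level.
#' @export
dividing_phase <- function(x, config = clus_config()) {
  stopifnot(inherits(x, "cohort"))
  scores <- x$scores
  nodes <- list(list(id = 1L, members = seq_len(nrow(scores)), level = 1L,
                     parent = NA_integer_, children = NULL, split = NULL,
                     tag = "1"))
  queue <- 1L
  while (length(queue) > 0L) {
    nid <- queue[[1L]]
    queue <- queue[-1L]
    nd <- nodes[[nid]]
    sp <- find_split(scores[nd$members, , drop = FALSE], config)
    if (is.null(sp)) next
    halves <- split_class(scores[nd$members, , drop = FALSE], sp)
    lid <- length(nodes) + 1L
    rid <- lid + 1L
    child_tag <- paste0(nd$tag, nd$level + 1L)  # display only, as drawn in a level-tag tree
    nodes[[lid]] <- list(id = lid, members = nd$members[halves$left],
                         level = nd$level + 1L, parent = nid, children = NULL,
                         split = NULL, tag = child_tag)
    nodes[[rid]] <- list(id = rid, members = nd$members[halves$right],
                         level = nd$level + 1L, parent = nid, children = NULL,
                         split = NULL, tag = child_tag)
    nodes[[nid]]$children <- c(lid, rid)
    nodes[[nid]]$split <- sp
    queue <- c(queue, lid, rid)
  }
  structure(list(nodes = nodes, ids = x$ids,
                 max_level = max(vapply(nodes, `[[`, integer(1), "level"))),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  leaves <- sum(vapply(x$nodes, function(nd) is.null(nd$children), logical(1)))
  cat(sprintf("<cluster_tree> %d nodes, %d leaves, depth %d, %d athletes\n",
              length(x$nodes), leaves, x$max_level, length(x$ids)))
  invisible(x)
}

#' Should two sibling subclasses be merged?
#'
#' Two siblings merge iff the dividing criterion cannot re-split their
#' union: [find_split()] on the pooled members returns `NULL`. This reuses
#' the dividing phase's own sample-distribution test, so the two phases stay
#' mutually consistent. Symmetric in its arguments; identical member sets
#' merge trivially.
#'
#' @param members1,members2 integer row indices (or id vectors resolvable
#'   against `x$ids`) of the two sibling classes.
#' @param x the [cohort()] the indices refer to.
#' @param config a [clus_config()].
#' @return TRUE iff the union is not re-splittable.
#' @export
merge_condition <- function(members1, members2, x, config = clus_config()) {
  scores <- as_score_matrix(x)
  resolve <- function(m) {
    if (is.character(m)) match(m, rownames(scores)) else as.integer(m)
  }
  m1 <- resolve(members1)
  m2 <- resolve(members2)
  if (setequal(m1, m2)) return(TRUE)
  u <- union(m1, m2)
  is.null(find_split(scores[u, , drop = FALSE], config))
}

#' Agglomerating phase: re-merge sibling subclasses bottom-up
#'
#' Walks the dividing tree deepest level first. A sibling pair is examined
#' only once both sides have themselves collapsed to single clusters; if
#' [merge_condition()] holds, the pair is replaced by its parent (one
#' cluster, level decremented), otherwise the two children stand and the
#' parent is abandoned -- its ancestors can then never merge across this
#' boundary, so the children become final clusters. Terminates at the root.
#'
#' @param tree a `cluster_tree` from [dividing_phase()].
#' @param x the [cohort()] the tree was built from.
#' @param config a [clus_config()].
#' @return a [partition()] of the cohort.
#' @export
agglomerating_phase <- function(tree, x, config = clus_config()) {
  stopifnot(inherits(tree, "cluster_tree"), inherits(x, "cohort"))
  scores <- x$scores
  collapse <- function(nid) {
    nd <- tree$nodes[[nid]]
    if (is.null(nd$children)) return(list(nd$members))
    l <- collapse(nd$children[[1L]])
    r <- collapse(nd$children[[2L]])
    if (length(l) == 1L && length(r) == 1L &&
        merge_condition(l[[1L]], r[[1L]], x, config)) {
      list(nd$members)
    } else {
      c(l, r)
    }
  }
  clusters <- collapse(1L)
  partition(lapply(clusters, function(m) tree$ids[m]), tree$ids)
}

#' Two-phase clustering of an athlete cohort
#'
#' Runs [dividing_phase()] then [agglomerating_phase()]. Deterministic for
#' a fixed cohort and configuration.
#'
#' @param x a [cohort()].
#' @param config a [clus_config()].
#' @return list with `partition` (a [partition()]) and `tree` (the
#'   `cluster_tree` from the dividing phase).
#' @export
#' @examples
#' set.seed(1)
#' m <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 8), ncol = 2))
#' res <- cluster_cohort(cohort(m))
#' length(res$partition$clusters)
cluster_cohort <- function(x, config = clus_config()) {
  tree <- dividing_phase(x, config)
  part <- agglomerating_phase(tree, x, config)
  list(partition = part, tree = tree)
}

#' Export a dividing tree as nested JSON
#'
#' @param tree a `cluster_tree`.
#' @param path output file; when NULL the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
tree_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "cluster_tree"))
  as_list <- function(nid) {
    nd <- tree$nodes[[nid]]
    out <- list(tag = nd$tag, level = nd$level,
                members = tree$ids[nd$members])
    if (!is.null(nd$split)) {
      out$split <- list(dim = nd$split$dim, threshold = nd$split$threshold)
      out$children <- lapply(nd$children, as_list)
    }
    out
  }
  js <- jsonlite::toJSON(as_list(1L), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
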