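# Independent oracles used to cross-check the implementation.

# Exhaustive split-search oracle: enumerates every (dimension, bin) pair
# with plain loops and comparison-based counting, applies the documented
# candidate and validity rules, and returns the best valid split (or NULL).
# Deliberately written with different primitives than find_split.
oracle_find_split <- function(scores, bins = 16L, min_cluster_size = 2L,
                              window = 3L) {
  n <- nrow(scores)
  B <- min(bins, as.integer(ceiling(sqrt(n))))
  if (B < 2L || n < 2L * min_cluster_size) return(NULL)
  movavg <- function(cnt) {
    k <- (window - 1L) %/% 2L
    sapply(seq_along(cnt), function(j) {
      lo <- max(1L, j - k)
      hi <- min(length(cnt), j + k)
      sum(cnt[lo:hi]) / (hi - lo + 1L)
    })
  }
  count_in <- function(x, edges) {
    # comparison-based binning, clamped to [1, B], last bin right-closed
    cnt <- integer(B)
    for (j in seq_len(B)) {
      if (j < B) {
        cnt[j] <- sum(x >= edges[j] & x < edges[j + 1L])
      } else {
        cnt[j] <- sum(x >= edges[j] & x <= edges[j + 1L])
      }
    }
    cnt[1L] <- cnt[1L] + sum(x < edges[1L])
    cnt[B] <- cnt[B] + sum(x > edges[B + 1L])
    cnt
  }
  best <- NULL
  for (i in seq_len(ncol(scores))) {
    v <- scores[, i]
    if (min(v) == max(v)) next
    edges <- seq(min(v), max(v), length.out = B + 1L)
    cnt <- count_in(v, edges)
    s <- movavg(cnt)
    for (b in 2:(B - 1L)) {
      is_min <- s[b] <= s[b - 1L] && s[b] <= s[b + 1L] &&
        (s[b] < s[b - 1L] || s[b] < s[b + 1L])
      if (!is_min) next
      if (s[b] >= n / B - 2 * sqrt(n / B)) next
      inbin <- if (b < B) v >= edges[b] & v < edges[b + 1L] else
        v >= edges[b] & v <= edges[b + 1L]
      thr <- if (any(inbin)) stats::median(v[inbin]) else
        (edges[b] + edges[b + 1L]) / 2
      n1 <- sum(v <= thr)
      if (n1 < min_cluster_size || n - n1 < min_cluster_size) next
      peak1 <- max(movavg(count_in(v[v <= thr], edges)))
      peak2 <- max(movavg(count_in(v[v > thr], edges)))
      if (!(peak1 > n / B && peak2 > n / B)) next
      depth <- min(max(s[1:(b - 1L)]), max(s[(b + 1L):B])) - s[b]
      if (depth <= 0) next
      if (is.null(best) || depth > best$depth) {
        best <- list(dim = i, threshold = thr, bin = b, depth = depth)
      }
    }
  }
  best
}

# Central finite-difference gradients of the batch error, perturbing every
# free parameter of the network in turn.
fd_gradients <- function(net, X, targets, h = 1e-6) {
  grad_of <- function(set, len) {
    vapply(seq_len(len), function(i) {
      (total_error(set(net, i, +h), X, targets) -
         total_error(set(net, i, -h), X, targets)) / (2 * h)
    }, numeric(1))
  }
  k <- net$k
  d <- net$d
  list(
    weights = grad_of(function(o, i, e) {
      o$weights[i] <- o$weights[i] + e
      o
    }, k),
    centers = matrix(grad_of(function(o, i, e) {
      o$centers[i] <- o$centers[i] + e
      o
    }, k * d), k, d),
    widths = grad_of(function(o, i, e) {
      o$widths[i] <- o$widths[i] + e
      o
    }, k)
  )
}

# Planted Gaussian blob cohort: k classes in d dimensions, class j elevated
# in its own block of coordinates (dimensions assigned round-robin).
make_blobs <- function(n_per = 100L, sep = 5, sd = 0.8, seed = 1L, d = 12L,
                       k = 3L) {
  set.seed(seed)
  centers <- matrix(0, k, d)
  assign_cls <- rep_len(seq_len(k), d)
  for (j in seq_len(k)) centers[j, assign_cls == j] <- sep
  lab <- rep(seq_len(k), each = n_per)
  m <- centers[lab, , drop = FALSE] +
    matrix(stats::rnorm(k * n_per * d, 0, sd), k * n_per, d)
  list(cohort = cohort(m, ids = paste0("P", seq_len(k * n_per))), labels = lab)
}

# random small network + batch for gradient property tests
random_rbf_instance <- function(seed, k = 3L, d = 2L, n = 5L) {
  set.seed(seed)
  codes <- seq_len(k)
  names(codes) <- paste0("cls", seq_len(k))
  net <- rbf_network(matrix(stats::rnorm(k * d), k, d),
                     stats::runif(k, 0.5, 2), stats::rnorm(k),
                     class_codes = codes)
  list(net = net,
       X = matrix(stats::rnorm(n * d), n, d),
       targets = sample(seq_len(k), n, replace = TRUE))
}

# floor = 1e-3: central differences with h = 1e-6 carry absolute noise of
# about eps * xi / h ~ 1e-9, so partials smaller than ~1e-4 cannot be
# certified to a relative 1e-5; the floor keeps the comparison meaningful
max_rel_err <- function(analytic, numeric, floor = 1e-3) {
  a <- unlist(analytic)
  b <- unlist(numeric)
  max(abs(a - b) / pmax(abs(a), floor))
}
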