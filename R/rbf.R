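# Gaussian RBF network for anxiety-state classification: k = 3 hidden units
# (one per anxiety class), a single weighted-sum output approximating the
# integer class code, and full batch gradient descent on output weights,
# centers and widths.

#' Default anxiety-class to target-code mapping
#'
#' Physical-condition anxiety carries code 3; the codes for competition and
#' cognitive anxiety are a package convention (1 and 2) and can be remapped
#' via the `class_codes` arguments.
#'
#' @return named integer vector mapping class names to codes in {1, 2, 3}.
#' @export
default_class_codes <- function() {
  c(competition = 1L, cognitive = 2L, physical = 3L)
}

check_class_codes <- function(class_codes) {
  if (is.null(names(class_codes)) || anyDuplicated(names(class_codes)) ||
      !setequal(class_codes, seq_along(class_codes))) {
    stop("class_codes must be a named bijection onto 1..k")
  }
  storage.mode(class_codes) <- "integer"
  class_codes
}

#' Construct an RBF network
#'
#' @param centers k x d numeric matrix of hidden-unit centers, one row per
#'   anxiety class (rows named by class).
#' @param widths k positive Gaussian widths.
#' @param weights k output weights.
#' @param class_codes named bijection class -> code in {1..k}; see
#'   [default_class_codes()].
#' @return an object of class `rbf_network`.
#' @export
rbf_network <- function(centers, widths, weights,
                        class_codes = default_class_codes()) {
  centers <- as.matrix(centers)
  class_codes <- check_class_codes(class_codes)
  k <- nrow(centers)
  if (length(widths) != k || length(weights) != k) {
    stop("centers, widths and weights must agree on k")
  }
  if (any(widths <= 0)) stop("all widths must be positive")
  if (k != length(class_codes)) stop("class_codes must have one entry per hidden unit")
  rownames(centers) <- names(class_codes)
  structure(list(centers = centers, widths = as.numeric(widths),
                 weights = as.numeric(weights), k = k, d = ncol(centers),
                 class_codes = class_codes),
            class = "rbf_network")
}

#' @export
print.rbf_network <- function(x, ...) {
  cat(sprintf("<rbf_network> k = %d Gaussian units, d = %d inputs\n", x$k, x$d))
  cat("widths:", signif(x$widths, 4), "\n")
  cat("weights:", signif(x$weights, 4), "\n")
  invisible(x)
}

#' Gaussian activation of one hidden unit
#'
#' `R_j(x) = exp(-||x - c_j||^2 / (2 sigma_j^2))`, in (0, 1].
#'
#' @param x input vector.
#' @param center unit center, same length as `x`.
#' @param width positive Gaussian width sigma_j.
#' @return a single number in (0, 1\].
#' @export
gaussian_activation <- function(x, center, width) {
  if (width <= 0) stop("width must be positive")
  if (length(x) != length(center)) stop("dimension mismatch")
  exp(-sum((x - center)^2) / (2 * width^2))
}

# n x k activation matrix for a batch (rows of X)
rbf_activations <- function(net, X) {
  X <- as_score_matrix(X)
  if (ncol(X) != net$d) stop("dimension mismatch: network expects d = ", net$d)
  d2 <- outer(rowSums(X^2), rowSums(net$centers^2), `+`) -
    2 * X %*% t(net$centers)
  d2[d2 < 0] <- 0  # numerical guard
  exp(sweep(d2, 2, -2 * net$widths^2, `/`))
}

#' Network output for a batch of inputs
#'
#' `y(x) = sum_j w_j R_j(x)`: the scalar output approximating the target
#' class code.
#'
#' @param net an [rbf_network()].
#' @param X input matrix (rows = samples) or a [cohort()]; a bare vector is
#'   treated as a single sample.
#' @return numeric vector of outputs, one per row.
#' @export
rbf_forward <- function(net, X) {
  if (is.null(dim(X)) && !inherits(X, "cohort")) X <- matrix(X, nrow = 1L)
  drop(rbf_activations(net, X) %*% net$weights)
}

#' Batch error function
#'
#' `xi = 1/2 sum_q (d_q - y(x_q))^2` over the whole batch.
#'
#' @param net an [rbf_network()].
#' @param X batch inputs (matrix or cohort).
#' @param targets numeric target codes d_q, one per row of `X`.
#' @return a single non-negative number; 0 iff every residual is 0.
#' @export
total_error <- function(net, X, targets) {
  if (is.null(dim(X)) && !inherits(X, "cohort")) X <- matrix(X, nrow = 1L)
  X <- as_score_matrix(X)
  if (nrow(X) == 0L) stop("empty batch")
  if (nrow(X) != length(targets)) stop("targets must match the batch size")
  e <- targets - rbf_forward(net, X)
  sum(e^2) / 2
}

#' Analytic gradients of the batch error
#'
#' For each hidden unit j, with residuals `e_q = d_q - y(x_q)`:
#' \describe{
#'   \item{weights}{`-sum_q e_q R_j(x_q)`}
#'   \item{centers}{`-sum_q e_q (w_j / sigma_j^2) R_j(x_q) (x_q - c_j)`}
#'   \item{widths}{`-sum_q e_q (w_j / sigma_j^3) ||x_q - c_j||^2 R_j(x_q)`}
#' }
#'
#' @param net an [rbf_network()].
#' @param X batch inputs.
#' @param targets target codes, one per row.
#' @return list with `weights` (k), `centers` (k x d), `widths` (k).
#' @export
rbf_gradients <- function(net, X, targets) {
  if (is.null(dim(X)) && !inherits(X, "cohort")) X <- matrix(X, nrow = 1L)
  X <- as_score_matrix(X)
  if (nrow(X) != length(targets)) stop("targets must match the batch size")
  A <- rbf_activations(net, X)
  e <- targets - drop(A %*% net$weights)
  gw <- -unname(drop(crossprod(A, e)))
  gc <- matrix(0, net$k, net$d)
  gs <- numeric(net$k)
  for (j in seq_len(net$k)) {
    ea <- e * A[, j]
    diff <- sweep(X, 2, net$centers[j, ], `-`)
    gc[j, ] <- -(net$weights[j] / net$widths[j]^2) * colSums(ea * diff)
    gs[j] <- -(net$weights[j] / net$widths[j]^3) * sum(ea * rowSums(diff^2))
  }
  dimnames(gc) <- dimnames(net$centers)
  list(weights = gw, centers = gc, widths = gs)
}

#' One gradient-descent parameter update
#'
#' Applies `theta <- theta - eta * grad` with a separate learning rate per
#' parameter family (eta_w for weights, eta_c for centers, eta_s for
#' widths). Widths are floored at `sigma_min` so a large step can never
#' produce a non-positive Gaussian width.
#'
#' @param net an [rbf_network()].
#' @param grads gradients from [rbf_gradients()].
#' @param config a [train_config()].
#' @return the updated `rbf_network`.
#' @export
update_step <- function(net, grads, config = train_config()) {
  net$weights <- net$weights - config$eta_w * grads$weights
  net$centers <- net$centers - config$eta_c * grads$centers
  net$widths <- pmax(net$widths - config$eta_s * grads$widths, config$sigma_min)
  net
}

#' Training configuration
#'
#' The default learning rates differ by parameter family: output weights
#' are linear parameters and tolerate the largest stable step (0.005 for
#' batch gradients that scale with N ~ 500), widths adapt more slowly
#' (0.002), and centers -- the most sensitive parameters,
#' whose displacement directly distorts the class prototypes -- slowest of
#' all (5e-5). A single shared rate large enough to fit the output weights
#' oscillates early in training and drags the centers far from the class
#' means they are initialized at.
#'
#' @param eta_w,eta_c,eta_s positive learning rates for output weights,
#'   centers and widths.
#' @param epsilon error tolerance: training stops once the batch error
#'   `xi` drops below it. `NULL` (the default) means `0.01 * N`, chosen at
#'   training time, i.e. a mean squared residual of about 0.02.
#' @param max_iter maximum number of epochs MaxT (>= 0).
#' @param sigma_min floor applied to widths during initialization and
#'   updates.
#' @param seed recorded for provenance; training itself is deterministic.
#' @return a list of class `train_config`.
#' @export
train_config <- function(eta_w = 0.005, eta_c = 5e-5, eta_s = 2e-3,
                         epsilon = NULL, max_iter = 5000L, sigma_min = 1e-3,
                         seed = 1L) {
  if (any(c(eta_w, eta_c, eta_s, sigma_min) <= 0)) {
    stop("learning rates and sigma_min must be positive")
  }
  if (!is.null(epsilon) && epsilon <= 0) stop("epsilon must be positive")
  max_iter <- as.integer(max_iter)
  if (max_iter < 0L) stop("max_iter must be >= 0")
  structure(list(eta_w = eta_w, eta_c = eta_c, eta_s = eta_s,
                 epsilon = epsilon, max_iter = max_iter,
                 sigma_min = sigma_min, seed = as.integer(seed)),
            class = "train_config")
}

#' Class-statistics initialization of the network
#'
#' Each hidden unit takes the mean of its class's samples as the initial
#' center and the mean Euclidean distance of those samples to the center as
#' the initial width (floored at `sigma_min`). Initial output weights solve
#' the k x k linear system `R w = d` built from one representative sample
#' per class -- the sample nearest its class center -- with a tiny ridge
#' fallback when the system is singular.
#'
#' @param X sample matrix or [cohort()].
#' @param labels anxiety class per sample; values must be names of
#'   `class_codes`.
#' @param class_codes named bijection class -> code.
#' @param sigma_min width floor.
#' @return an [rbf_network()].
#' @export
init_network <- function(X, labels, class_codes = default_class_codes(),
                         sigma_min = 1e-3) {
  X <- as_score_matrix(X)
  class_codes <- check_class_codes(class_codes)
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) stop("labels must match the number of samples")
  unknown <- setdiff(unique(labels), names(class_codes))
  if (length(unknown) > 0L) {
    stop("labels outside class_codes: ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(names(class_codes), unique(labels))
  if (length(missing) > 0L) {
    stop("empty class: ", paste(missing, collapse = ", "))
  }
  k <- length(class_codes)
  d <- ncol(X)
  centers <- matrix(0, k, d, dimnames = list(names(class_codes), colnames(X)))
  widths <- numeric(k)
  reps <- matrix(0, k, d)
  for (j in seq_len(k)) {
    cls <- names(class_codes)[j]
    Xc <- X[labels == cls, , drop = FALSE]
    centers[j, ] <- colMeans(Xc)
    dist <- sqrt(rowSums(sweep(Xc, 2, centers[j, ], `-`)^2))
    widths[j] <- max(mean(dist), sigma_min)
    reps[j, ] <- Xc[which.min(dist), ]
  }
  net <- rbf_network(centers, widths, weights = rep(0, k),
                     class_codes = class_codes)
  R <- rbf_activations(net, reps)
  targets <- as.numeric(class_codes)
  w <- tryCatch(solve(R, targets), error = function(e) {
    solve(crossprod(R) + diag(1e-8, k), crossprod(R, targets))
  })
  net$weights <- as.numeric(w)
  net
}

#' Train the RBF network by batch gradient descent
#'
#' Initializes with [init_network()], then iterates: compute the batch
#' error `xi(t)`; stop as soon as `xi < epsilon` (converged) or after
#' `max_iter` epochs (not converged); otherwise take one [update_step()] on
#' the full-batch gradients. One iteration is one epoch over all samples --
#' the gradient formulas sum over the whole batch. Deterministic for fixed
#' inputs and configuration.
#'
#' @param X sample matrix or [cohort()].
#' @param labels anxiety class per sample.
#' @param config a [train_config()].
#' @param class_codes named bijection class -> code.
#' @return list of class `rbf_train_result`: `network`, `converged`,
#'   `iterations`, and `error_trace` (xi after 0, 1, ... updates).
#' @export
rbf_train <- function(X, labels, config = train_config(),
                      class_codes = default_class_codes()) {
  X <- as_score_matrix(X)
  net <- init_network(X, labels, class_codes, config$sigma_min)
  targets <- as.numeric(net$class_codes[as.character(labels)])
  eps <- config$epsilon %||% (0.01 * nrow(X))
  xi <- total_error(net, X, targets)
  trace <- xi
  iter <- 0L
  while (xi >= eps && iter < config$max_iter) {
    net <- update_step(net, rbf_gradients(net, X, targets), config)
    iter <- iter + 1L
    xi <- total_error(net, X, targets)
    trace <- c(trace, xi)
  }
  structure(list(network = net, converged = xi < eps, iterations = iter,
                 error_trace = trace),
            class = "rbf_train_result")
}

#' @export
print.rbf_train_result <- function(x, ...) {
  cat(sprintf("<rbf_train_result> %s after %d epochs; xi: %.4g -> %.4g\n",
              if (x$converged) "converged" else "not converged",
              x$iterations, x$error_trace[1L],
              x$error_trace[length(x$error_trace)]))
  invisible(x)
}

#' Predict the anxiety risk level (1/2/3)
#'
#' The scalar network output is rounded to the nearest integer code (half
#' up) and clipped to \[1, k\]: 1 low, 2 medium, 3 high risk.
#'
#' @param net a trained [rbf_network()].
#' @param X inputs (matrix, cohort, or a single vector).
#' @return integer vector of risk levels.
#' @export
predict_risk <- function(net, X) {
  y <- rbf_forward(net, X)
  as.integer(pmin(pmax(floor(y + 0.5), 1), net$k))
}

#' Predict the anxiety class
#'
#' Inverse of the class-code mapping applied to [predict_risk()].
#'
#' @param net a trained [rbf_network()].
#' @param X inputs.
#' @return character vector of class names (e.g. "physical").
#' @export
predict_class <- function(net, X) {
  codes <- predict_risk(net, X)
  names(net$class_codes)[match(codes, net$class_codes)]
}

#' Persist a trained network (with optional training metadata) as JSON
#'
#' Round-trips exactly through [read_rbf()] for all stored digits.
#'
#' @param x an `rbf_network` or `rbf_train_result`.
#' @param path output JSON file.
#' @param metadata optional named list stored alongside the parameters.
#' @return `path`, invisibly.
#' @export
write_rbf <- function(x, path, metadata = NULL) {
  if (inherits(x, "rbf_train_result")) {
    metadata <- c(metadata %||% list(),
                  list(converged = x$converged, iterations = x$iterations,
                       final_error = x$error_trace[length(x$error_trace)]))
    x <- x$network
  }
  stopifnot(inherits(x, "rbf_network"))
  obj <- list(k = x$k, d = x$d, centers = unname(x$centers),
              widths = x$widths, weights = x$weights,
              class_codes = as.list(x$class_codes),
              factor_names = colnames(x$centers))
  if (!is.null(metadata)) obj$metadata <- metadata
  # digits = I(17): 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Load a network persisted by [write_rbf()]
#'
#' @param path JSON file path.
#' @return an [rbf_network()]; any stored metadata is attached as the
#'   `metadata` attribute.
#' @export
read_rbf <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  centers <- matrix(as.numeric(obj$centers), nrow = obj$k)
  if (!is.null(obj$factor_names)) colnames(centers) <- obj$factor_names
  codes <- unlist(obj$class_codes)
  net <- rbf_network(centers, obj$widths, obj$weights, class_codes = codes)
  if (!is.null(obj$metadata)) attr(net, "metadata") <- obj$metadata
  net
}
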