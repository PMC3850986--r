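#' Fit a 1-norm regularized linear classifier (1-norm SVM)
#'
#' Solves, as a linear program,
#' \deqn{\min_{w,b,\xi} \; \lambda \sum_k |w_k| + \sum_i \xi_i
#'   \quad \mathrm{s.t.} \quad y_i (w \cdot x_i + b) \ge 1 - \xi_i,\; \xi_i \ge 0,}
#' via the standard split \eqn{w = u - v}, \eqn{u, v \ge 0}. The 1-norm
#' penalty drives many weights exactly to zero, so the fitted model doubles
#' as a feature selector: the support (non-zero weights) is the selected
#' concept/feature set. The LP is solved by the package's dense simplex
#' (exact vertex solution; tolerance ~1e-9).
#'
#' @param X numeric samples-by-features matrix.
#' @param y +1/-1 label per sample; both classes must be present.
#' @param lambda positive regularization strength (large values shrink all
#'   weights to zero).
#' @param feature_ids optional feature names (default from columns).
#' @return Object of class \code{"one_norm_fit"}: \code{weights},
#'   \code{intercept}, \code{lambda}, \code{objective},
#'   \code{support_tolerance} (resolved as
#'   \code{1e-8 * max(1, max |w|)}), \code{feature_ids}.
#' @export
fit_one_norm <- function(X, y, lambda, feature_ids = NULL) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!all(y %in% c(-1, 1))) stop("labels must be +1 or -1")
  if (length(unique(y)) < 2L)
    stop("both classes must be present to fit a classifier")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("lambda must be a positive number")
  if (!all(is.finite(X))) stop("non-finite entries in X")
  sol <- .one_norm_lp_cpp(X, y, lambda)
  if (sol$status != 0L)
    stop("LP solver failed (status ", sol$status,
         " after ", sol$iterations, " iterations)")
  w <- as.numeric(sol$w)
  structure(
    list(weights = w, intercept = sol$b, lambda = lambda,
         objective = sol$objective,
         support_tolerance = 1e-8 * max(1, max(abs(w))),
         feature_ids = feature_ids %||% colnames(X) %||%
           paste0("f", seq_len(ncol(X)))),
    class = "one_norm_fit")
}

#' @export
print.one_norm_fit <- function(x, ...) {
  cat(sprintf("1-norm linear fit: %d/%d non-zero weights, b = %.4g, lambda = %.3g\n",
              length(support(x)), length(x$weights), x$intercept, x$lambda))
  invisible(x)
}

#' Support (non-zero weight) indices of a fitted model
#'
#' Indices k with |w_k| above the model's support tolerance. LP solvers
#' return tiny non-zeros, so "non-zero" is a numerical tolerance, resolved
#' at fit time relative to the largest weight. Signs partition the support
#' into positive prototypes (w > 0) and negative prototypes (w < 0);
#' zero-weight concepts are void prototypes and never affect predictions.
#'
#' @param m a \code{one_norm_fit}.
#' @param tolerance override the model's stored tolerance.
#' @return Integer index vector (possibly empty).
#' @export
support <- function(m, tolerance = m$support_tolerance) {
  which(abs(m$weights) > tolerance)
}

#' Predict the label of one embedded bag
#'
#' The bag decision rule:
#' \eqn{\hat y = \mathrm{sign}(\sum_{k \in I} w_k\, s(x^k, B_i) + b)},
#' computed solely over the support I (void concepts contribute nothing;
#' the sum equals the full dot product). \code{sign(0)} resolves to +1.
#'
#' @param m a \code{one_norm_fit}.
#' @param bag_embedding numeric vector of per-concept similarities for one
#'   bag (one entry per model weight), or a matrix with one column per bag.
#' @return +1/-1, one per bag.
#' @export
predict_bag <- function(m, bag_embedding) {
  s <- as.matrix(bag_embedding)
  if (nrow(s) == 1L && length(m$weights) > 1L) s <- t(s)
  if (nrow(s) != length(m$weights))
    stop("embedding dimension does not match the model")
  i <- support(m)
  dec <- if (length(i) == 0L) rep(0, ncol(s))
         else as.numeric(crossprod(s[i, , drop = FALSE], m$weights[i]))
  sign0(dec + m$intercept)
}

#' @export
predict.one_norm_fit <- function(object, newdata, ...) {
  # newdata: samples x features, as in fit_one_norm()
  predict_bag(object, t(as.matrix(newdata)))
}

#' Choose the regularization strength by cross-validation
#'
#' Stratified, seeded k-fold assignment at the sample (bag) level; for each
#' lambda on the grid the mean fold misclassification rate is computed, and
#' the lambda with the smallest mean error is chosen, ties broken toward
#' the larger (sparser) lambda. The returned \code{cv_error} is the mean
#' cross-validation error at the chosen lambda.
#'
#' @param X,y as in \code{\link{fit_one_norm}}.
#' @param grid vector of positive lambdas (default
#'   \code{10^seq(-3, 2, length.out = 13)}).
#' @param folds number of folds (>= 2, at most the smaller class size).
#' @param seed integer seed for the fold assignment.
#' @return Object of class \code{"cv_one_norm"}: \code{lambda_grid},
#'   \code{fold_errors} (lambda x fold), \code{mean_errors},
#'   \code{chosen_lambda}, \code{cv_error}, \code{fold_of}.
#' @export
select_lambda <- function(X, y, grid = 10^seq(-3, 2, length.out = 13),
                          folds = 10, seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (length(grid) < 1L || any(grid <= 0)) stop("lambda grid must be positive")
  grid <- sort(grid)
  if (folds < 2L) stop("folds must be at least 2")
  if (folds > min(table(y)))
    stop("more folds than members of the smaller class")
  fold_of <- integer(length(y))
  with_seed(seed, for (cl in c(-1, 1)) {
    idx <- sample(which(y == cl))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  })
  fe <- matrix(NA_real_, length(grid), folds)
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    for (g in seq_along(grid)) {
      m <- fit_one_norm(X[tr, , drop = FALSE], y[tr], grid[g])
      fe[g, f] <- mean(predict(m, X[!tr, , drop = FALSE]) != y[!tr])
    }
  }
  me <- rowMeans(fe)
  best <- max(which(me == min(me)))   # ties -> larger lambda
  structure(
    list(lambda_grid = grid, fold_errors = fe, mean_errors = me,
         chosen_lambda = grid[best], cv_error = me[best], fold_of = fold_of),
    class = "cv_one_norm")
}

#' @export
print.cv_one_norm <- function(x, ...) {
  cat(sprintf("%d-fold CV over %d lambdas: chosen lambda = %.3g, CV error = %.4f\n",
              ncol(x$fold_errors), length(x$lambda_grid),
              x$chosen_lambda, x$cv_error))
  invisible(x)
}

#' Serialize a fitted model to JSON (support weights only)
#'
#' @param m a \code{one_norm_fit}.
#' @param path file to write.
#' @param similarity_kind,sigma optional embedding metadata stored
#'   alongside the weights.
#' @export
write_model <- function(m, path, similarity_kind = NULL, sigma = NULL) {
  i <- support(m)
  obj <- list(
    lambda = m$lambda, b = m$intercept,
    support_tolerance = m$support_tolerance,
    weights = lapply(i, function(k)
      list(feature_id = m$feature_ids[k], index = k, w = m$weights[k])),
    n_features = length(m$weights))
  if (!is.null(similarity_kind)) obj$similarity_kind <- similarity_kind
  if (!is.null(sigma) && !is.na(sigma)) obj$sigma <- sigma
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Read a model written by \code{\link{write_model}}
#' @param path file to read.
#' @return A \code{one_norm_fit} (zero weights off the stored support).
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  w <- numeric(obj$n_features)
  ids <- paste0("f", seq_len(obj$n_features))
  for (e in obj$weights) {
    w[e$index] <- e$w
    ids[e$index] <- e$feature_id
  }
  structure(
    list(weights = w, intercept = obj$b, lambda = obj$lambda,
         objective = NA_real_, support_tolerance = obj$support_tolerance,
         feature_ids = ids),
    class = "one_norm_fit")
}
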