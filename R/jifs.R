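#' Configuration for the joint instance and feature selection loop
#'
#' @param lambda_grid positive lambdas for cross-validated selection
#'   (default logarithmic, 1e-3 .. 1e2, 13 points).
#' @param cv_folds folds for lambda selection (default 10).
#' @param k_per_bag instances selected per bag for the second-stage fit
#'   (default 2).
#' @param similarity_kind \code{"min_distance"} or \code{"gaussian_max"}.
#' @param sigma kernel width for \code{gaussian_max}.
#' @param use_mk_factor divide instance contributions by the multiplicity
#'   (default TRUE).
#' @param max_iterations safety cap on loop iterations (default 20; the
#'   loop normally stops much earlier, when no feature is eliminated).
#' @param finalization \code{"natural_stop"} (default: return the last
#'   iteration — backward elimination is the method's optional extra) or
#'   \code{"backward_elimination"} (return the iteration with minimum
#'   cross-validation error).
#' @param selection_rule see \code{\link{select_top_instances}}.
#' @param seed integer seed (fold assignment and repeats).
#' @param n_repeats repeats for \code{\link{repeat_and_pick}} (default 5).
#' @return A validated list of class \code{"jifs_config"}.
#' @export
jifs_config <- function(lambda_grid = 10^seq(-3, 2, length.out = 13),
                        cv_folds = 10, k_per_bag = 2,
                        similarity_kind = c("min_distance", "gaussian_max"),
                        sigma = 1, use_mk_factor = TRUE,
                        max_iterations = 20,
                        finalization = c("natural_stop", "backward_elimination"),
                        selection_rule = c("by_label", "ascending"),
                        seed = 1, n_repeats = 5) {
  cfg <- list(lambda_grid = as.numeric(lambda_grid),
              cv_folds = as.integer(cv_folds),
              k_per_bag = as.integer(k_per_bag),
              similarity_kind = match.arg(similarity_kind),
              sigma = as.numeric(sigma),
              use_mk_factor = isTRUE(use_mk_factor),
              max_iterations = as.integer(max_iterations),
              finalization = match.arg(finalization),
              selection_rule = match.arg(selection_rule),
              seed = as.integer(seed),
              n_repeats = as.integer(n_repeats))
  stopifnot(all(cfg$lambda_grid > 0), cfg$cv_folds >= 2L,
            cfg$k_per_bag >= 1L, cfg$sigma > 0,
            cfg$max_iterations >= 1L, cfg$n_repeats >= 1L)
  structure(cfg, class = "jifs_config")
}

#' Run the iterative joint instance and feature selection loop
#'
#' Each iteration: (1) embed all bags against the current concept set on
#' the current feature subset; (2) fit the 1-norm classifier in the
#' embedded space at a cross-validated lambda, recording the CV error;
#' (3) shrink the concept set to the fit's support (the prototype
#' concepts); (4) classify instances by contribution and select the
#' top-ranked instances per bag with their bag labels; (5) fit the 1-norm
#' classifier on those instances in the current original-feature subspace;
#' (6) drop the features with zero weight. The loop stops when an
#' iteration eliminates no feature, when it collapses (empty support or no
#' eligible instances — recorded as degenerate), or at the safety cap.
#'
#' Iteration 0 is a plain instance-embedded (MILES-style) fit with no
#' elimination applied yet; its record reports the full concept and
#' feature counts.
#'
#' @param train a \code{mil_dataset} with both classes.
#' @param cfg a \code{\link{jifs_config}}.
#' @return Object of class \code{"jifs_history"}: \code{iterations} (one
#'   record per iteration: iteration number, entry concept/feature sets as
#'   original indices, both fitted models, CV and training error, chosen
#'   lambdas), \code{stopped} (\code{"no_feature_drop"},
#'   \code{"degenerate"} or \code{"max_iterations"}), \code{config}, and
#'   the training data (needed to embed new bags at evaluation time).
#' @export
run_jifs <- function(train, cfg = jifs_config()) {
  stopifnot(inherits(train, "mil_dataset"))
  if (length(unique(train$bag_labels)) < 2L)
    stop("training data must contain both bag classes")
  feats <- seq_len(n_bits(train))
  concs <- seq_len(n_instances(train))
  iterations <- list()
  stopped <- "max_iterations"
  for (it in seq_len(cfg$max_iterations) - 1L) {
    dsub <- restrict_features(train, feats)
    cview <- restrict_concepts(dsub, concs)
    emb <- build_embedding(cview, dsub, cfg$similarity_kind, cfg$sigma)
    Xemb <- t(emb$values)
    y <- train$bag_labels
    cv1 <- select_lambda(Xemb, y, cfg$lambda_grid, cfg$cv_folds,
                         seed = cfg$seed + 2L * it)
    m1 <- fit_one_norm(Xemb, y, cv1$chosen_lambda,
                       feature_ids = emb$concept_ids)
    train_err <- mean(predict_bag(m1, emb$values) != y)
    rec <- list(iteration = it, concepts = concs, features = feats,
                n_concepts = length(concs), n_features = length(feats),
                cv_error = cv1$cv_error, train_error = train_err,
                model1 = m1, chosen_lambda = cv1$chosen_lambda,
                model2 = NULL, chosen_lambda2 = NA_real_,
                support = concs[support(m1)])
    i_sup <- support(m1)
    if (length(i_sup) == 0L) {
      iterations[[length(iterations) + 1L]] <- rec
      stopped <- "degenerate"; break
    }
    sel <- tryCatch(
      select_top_instances(dsub, m1, emb, cfg$k_per_bag,
                           cfg$use_mk_factor, cfg$selection_rule),
      error = function(e) NULL)
    if (is.null(sel) || length(unique(sel$y)) < 2L ||
        min(table(sel$y)) < cfg$cv_folds) {
      iterations[[length(iterations) + 1L]] <- rec
      stopped <- "degenerate"; break
    }
    cv2 <- select_lambda(sel$X, sel$y, cfg$lambda_grid, cfg$cv_folds,
                         seed = cfg$seed + 2L * it + 1L)
    m2 <- fit_one_norm(sel$X, sel$y, cv2$chosen_lambda,
                       feature_ids = dsub$feature_ids)
    rec$model2 <- m2
    rec$chosen_lambda2 <- cv2$chosen_lambda
    iterations[[length(iterations) + 1L]] <- rec
    keep <- support(m2)
    concs <- concs[i_sup]
    if (length(keep) == 0L) { stopped <- "degenerate"; break }
    if (length(keep) == length(feats)) { stopped <- "no_feature_drop"; break }
    feats <- feats[sort(keep)]
  }
  structure(
    list(iterations = iterations, stopped = stopped, config = cfg,
         train = train),
    class = "jifs_history")
}

#' @export
print.jifs_history <- function(x, ...) {
  cat(sprintf("joint selection history: %d iterations (stop: %s)\n",
              length(x$iterations), x$stopped))
  print(history_table(x))
  invisible(x)
}

#' Per-iteration summary table of a selection history
#' @param history a \code{jifs_history}.
#' @return data.frame with columns iteration, cv_error, train_error,
#'   n_concepts, n_features, chosen_lambda.
#' @export
history_table <- function(history) {
  do.call(rbind, lapply(history$iterations, function(r)
    data.frame(iteration = r$iteration, cv_error = r$cv_error,
               train_error = r$train_error, n_concepts = r$n_concepts,
               n_features = r$n_features, chosen_lambda = r$chosen_lambda)))
}

#' Write the per-iteration history table as TSV
#' @param history a \code{jifs_history}.
#' @param path file to write.
#' @export
write_history_tsv <- function(history, path) {
  utils::write.table(history_table(history), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Finalize a selection history
#'
#' \code{natural_stop} returns the last iteration; \code{backward_elimination}
#' returns the iteration with the minimum cross-validation error (earliest
#' iteration on ties). The finalized instance set C_f is the support of the
#' chosen iteration's embedded-space model (the prototype concepts); the
#' finalized feature set X_f is that iteration's feature subset.
#'
#' @param history a \code{jifs_history}.
#' @param mode finalization mode; defaults to the history's configuration.
#' @return List: \code{iteration} (the chosen record), \code{n_star},
#'   \code{concepts} (C_f, original instance-row indices), \code{features}
#'   (X_f, original bit indices), \code{cv_error}.
#' @export
finalize_jifs <- function(history,
                          mode = c("config", "backward_elimination", "natural_stop")) {
  mode <- match.arg(mode)
  if (mode == "config") mode <- history$config$finalization
  if (length(history$iterations) == 0L) stop("empty history")
  errs <- vapply(history$iterations, `[[`, numeric(1), "cv_error")
  n_star <- if (mode == "backward_elimination") which.min(errs)
            else length(history$iterations)
  rec <- history$iterations[[n_star]]
  list(iteration = rec, n_star = rec$iteration,
       concepts = rec$support, features = rec$features,
       cv_error = rec$cv_error)
}

#' Held-out error of a finalized selection
#'
#' Restricts the test bags to the finalized feature subset, embeds them
#' against the finalized iteration's concept set (taken from the training
#' data), and applies the bag decision rule. The test data must share the
#' original fingerprint space of the training data. Bags whose instances
#' are far from every prototype are still classified (possibly by the
#' intercept alone) — no bag is ever dropped.
#'
#' @param history a \code{jifs_history}.
#' @param test a \code{mil_dataset} in the original feature space.
#' @param mode see \code{\link{finalize_jifs}}.
#' @return Fraction of misclassified test bags, in [0, 1].
#' @export
evaluate_jifs <- function(history, test,
                          mode = c("config", "backward_elimination", "natural_stop")) {
  stopifnot(inherits(test, "mil_dataset"))
  if (n_bits(test) != n_bits(history$train))
    stop("test data does not share the training feature space")
  fin <- finalize_jifs(history, match.arg(mode))
  rec <- fin$iteration
  train_sub <- restrict_features(history$train, rec$features)
  test_sub <- restrict_features(test, rec$features)
  cview <- restrict_concepts(train_sub, rec$concepts)
  emb <- build_embedding(cview, test_sub, history$config$similarity_kind,
                         history$config$sigma)
  mean(predict_bag(rec$model1, emb$values) != test$bag_labels)
}

#' Repeat the selection loop and keep the best run
#'
#' Runs \code{\link{run_jifs}} with seeds \code{seed, seed + 1, ...} and
#' returns the run whose finalized cross-validation error is lowest
#' (i.e. maximum CV accuracy; earliest run on ties).
#'
#' @param train a \code{mil_dataset}.
#' @param cfg a \code{\link{jifs_config}}; \code{cfg$n_repeats} runs are
#'   performed.
#' @return The selected \code{jifs_history}, with attributes
#'   \code{"run_seeds"} and \code{"run_cv_errors"}.
#' @export
repeat_and_pick <- function(train, cfg = jifs_config()) {
  seeds <- cfg$seed + seq_len(cfg$n_repeats) - 1L
  runs <- lapply(seeds, function(s) {
    ci <- cfg; ci$seed <- s
    run_jifs(train, ci)
  })
  errs <- vapply(runs, function(h) finalize_jifs(h)$cv_error, numeric(1))
  best <- which.min(errs)
  out <- runs[[best]]
  attr(out, "run_seeds") <- seeds
  attr(out, "run_cv_errors") <- errs
  out
}
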