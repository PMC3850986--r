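# Driver tests run on a scaled-down planted family so the whole file
# stays fast; the full-size study conditions are exercised in
# test-acceptance.R.

small_cfg <- function(seed = 1, ...) {
  jifs_config(lambda_grid = 10^seq(-2, 1, length.out = 5),
              cv_folds = 4, seed = seed, ...)
}

test_that("the loop terminates and iteration 0 is a plain embedded-space fit", {
  gen <- small_planted(7, n_bags = 16, n_bits = 30, disc = 8)
  h <- run_jifs(gen$dataset, small_cfg(7))
  expect_s3_class(h, "jifs_history")
  expect_true(h$stopped %in% c("no_feature_drop", "degenerate", "max_iterations"))
  it0 <- h$iterations[[1]]
  expect_equal(it0$iteration, 0)
  expect_equal(it0$n_concepts, n_instances(gen$dataset))
  expect_equal(it0$n_features, n_bits(gen$dataset))
  ht <- history_table(h)
  # surviving sets never grow
  expect_true(all(diff(ht$n_features) <= 0))
  expect_true(all(diff(ht$n_concepts) <= 0))
})

test_that("finalization picks the argmin-error iteration, earliest on ties", {
  gen <- small_planted(8, n_bags = 16, n_bits = 30, disc = 8)
  h <- run_jifs(gen$dataset, small_cfg(8))
  errs <- history_table(h)$cv_error
  fake <- h
  fake$iterations <- h$iterations[rep(1, 3)]
  fake$iterations[[1]]$cv_error <- 0.20
  fake$iterations[[2]]$cv_error <- 0.10
  fake$iterations[[3]]$cv_error <- 0.15
  for (i in 1:3) fake$iterations[[i]]$iteration <- i - 1
  expect_equal(finalize_jifs(fake, "backward_elimination")$n_star, 1)
  expect_equal(finalize_jifs(fake, "natural_stop")$n_star, 2)
  # tie: earliest wins
  fake$iterations[[3]]$cv_error <- 0.10
  expect_equal(finalize_jifs(fake, "backward_elimination")$n_star, 1)
  # single-iteration history: both modes agree
  one <- h; one$iterations <- h$iterations[1]
  expect_equal(finalize_jifs(one, "backward_elimination")$n_star,
               finalize_jifs(one, "natural_stop")$n_star)
  # on the real history, backward elimination minimizes the recorded error
  expect_equal(finalize_jifs(h, "backward_elimination")$cv_error, min(errs))
})

test_that("held-out evaluation memorizes the training set and flips with labels", {
  gen <- small_planted(9, n_bags = 20, n_bits = 40, disc = 10)
  h <- run_jifs(gen$dataset, small_cfg(9))
  # test = train on separable planted data: near-zero error
  expect_lte(evaluate_jifs(h, gen$dataset), 0.1)
  flipped <- gen$dataset
  flipped$bag_labels <- -flipped$bag_labels
  expect_equal(evaluate_jifs(h, flipped), 1 - evaluate_jifs(h, gen$dataset))
  bad <- restrict_features(gen$dataset, 1:10)
  expect_error(evaluate_jifs(h, bad), "feature space")
})

test_that("held-out error on a 3:1 split of planted data is small", {
  # on fixtures this small the last iteration can collapse, so evaluate
  # at the minimum-CV-error iteration (backward elimination)
  errs <- vapply(1:3, function(s) {
    gen <- small_planted(20 + s, n_bags = 24, n_bits = 40, disc = 10)
    sp <- split_train_test(gen$dataset, 0.75, seed = s)
    h <- run_jifs(sp$train, small_cfg(20 + s))
    evaluate_jifs(h, sp$test, "backward_elimination")
  }, numeric(1))
  expect_lte(median(errs), 0.25)
})

test_that("histories are bit-identical under identical seed and config", {
  gen <- small_planted(10, n_bags = 14, n_bits = 24, disc = 6)
  h1 <- run_jifs(gen$dataset, small_cfg(10))
  h2 <- run_jifs(gen$dataset, small_cfg(10))
  expect_identical(h1, h2)
})

test_that("predictions are unchanged by deleting eliminated features and concepts", {
  gen <- small_planted(11, n_bags = 16, n_bits = 30, disc = 8)
  h <- run_jifs(gen$dataset, small_cfg(11))
  fin <- finalize_jifs(h)
  rec <- fin$iteration
  test <- gen$dataset
  # full evaluation path
  full <- {
    tr <- restrict_features(h$train, rec$features)
    emb <- build_embedding(restrict_concepts(tr, rec$concepts),
                           restrict_features(test, rec$features))
    predict_bag(rec$model1, emb$values)
  }
  # drop zero-weight concepts from model and embedding: same predictions
  keep <- support(rec$model1)
  m_small <- rec$model1
  m_small$weights <- m_small$weights[keep]
  m_small$feature_ids <- m_small$feature_ids[keep]
  tr <- restrict_features(h$train, rec$features)
  emb_small <- build_embedding(restrict_concepts(tr, rec$concepts[keep]),
                               restrict_features(test, rec$features))
  expect_equal(predict_bag(m_small, emb_small$values), full)
})

test_that("repeat_and_pick returns the lowest-error run deterministically", {
  gen <- small_planted(12, n_bags = 14, n_bits = 24, disc = 6)
  cfg <- small_cfg(12, n_repeats = 3)
  best <- repeat_and_pick(gen$dataset, cfg)
  errs <- attr(best, "run_cv_errors")
  expect_length(errs, 3)
  expect_equal(finalize_jifs(best)$cv_error, min(errs))
  expect_lte(finalize_jifs(best)$cv_error, median(errs))
  # n_repeats = 1 reduces to run_jifs
  cfg1 <- small_cfg(12, n_repeats = 1)
  r1 <- repeat_and_pick(gen$dataset, cfg1)
  attr(r1, "run_seeds") <- NULL; attr(r1, "run_cv_errors") <- NULL
  expect_identical(r1, run_jifs(gen$dataset, cfg1))
  # same seed, same selection
  best2 <- repeat_and_pick(gen$dataset, cfg)
  expect_identical(best, best2)
})

test_that("history table and TSV export carry the per-iteration record", {
  gen <- small_planted(13, n_bags = 14, n_bits = 24, disc = 6)
  h <- run_jifs(gen$dataset, small_cfg(13))
  ht <- history_table(h)
  expect_named(ht, c("iteration", "cv_error", "train_error", "n_concepts",
                     "n_features", "chosen_lambda"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_history_tsv(h, f)
  back <- utils::read.delim(f)
  expect_equal(back$n_features, ht$n_features)
})
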