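# The worked toy example: one bag of four instances, five signed concept
# targets, nearest-neighbor incidence fixed by construction.
fx <- figure1_fixture()
fx_emb <- build_embedding(fx$concepts, fx$dataset)

test_that("the toy fixture reproduces the worked example exactly", {
  # incidence recomputed from raw bit-strings matches the hard-coded one
  inc <- miljifs:::nearest_incidence(fx_emb, 1)
  expect_equal(unname(inc), unname(fx$expected$incidence))
  ca <- concept_assignments(1, fx$model, fx_emb)
  expect_equal(ca$U, fx$expected$U)
  expect_equal(unname(ca$mk), as.numeric(fx$expected$mk))
  ic <- classify_instances(1, fx$model, fx_emb, "fixed", threshold = 0)
  expect_equal(as.character(ic$class[1:3]), fx$expected$classes)
  # instance 4 sits exactly on the threshold: negative under g > delta
  expect_equal(ic$g[4], 0)
  expect_equal(as.character(ic$class[4]), "negative")
})

test_that("responsible sets are unions of per-concept argmin scans", {
  expect_equal(responsible_set(1, fx$model, fx_emb), c(1L, 2L, 4L))
  d <- random_dataset(n_bags = 6, n_bits = 10, max_inst = 5, seed = 51)
  ks <- c(1L, 3L, 6L, 9L)
  emb <- build_embedding(ks, d)
  m <- toy_model(c(1.2, -0.7, 0, 0.4))   # concept 3 is void
  for (b in seq_len(n_bags(d))) {
    rows <- bag_rows(d, b)
    u_brute <- sort(unique(unlist(lapply(support(m), function(ki) {
      ds <- apply(d$instances[rows, , drop = FALSE], 1, hamming_loop,
                  b = d$instances[ks[ki], ])
      which(ds == min(ds))
    }))))
    expect_equal(responsible_set(b, m, emb), u_brute)
  }
})

test_that("multiplicities count argmin ties and satisfy the double-counting identity", {
  # bag of identical instances: every concept ties across the whole bag
  d <- mil_dataset(matrix(1, 3, 4), c(1, 1, 1), 1)
  emb <- build_embedding(c(1L, 2L), d)
  m <- toy_model(c(1, -1))
  ca <- concept_assignments(1, m, emb)
  expect_equal(unname(ca$mk), c(3, 3))
  # double counting: sum of m^k equals sum of |I_j*|
  expect_equal(sum(ca$mk), sum(lengths(ca$assigned)))

  d <- random_dataset(n_bags = 8, n_bits = 6, max_inst = 5, seed = 61)
  ks <- c(2L, 5L, 7L)
  emb <- build_embedding(ks, d)
  m <- toy_model(c(0.5, 0.3, -0.9))
  for (b in seq_len(n_bags(d))) {
    ca <- concept_assignments(b, m, emb)
    expect_equal(sum(ca$mk), sum(lengths(ca$assigned)))
    expect_true(all(ca$mk >= 1))
  }
})

test_that("contribution arithmetic follows the weighted shared-similarity formula", {
  # one concept, one unambiguous nearest neighbor: g = w * s / m^k
  d <- mil_dataset(rbind(c(0, 0, 0, 0), c(1, 1, 1, 0)), c(1, 1), 1)
  other <- mil_dataset(matrix(c(1, 1, 0, 0), 1), 1, 1)
  emb <- build_embedding(restrict_concepts(other, 1L), d)
  m <- toy_model(2)
  expect_equal(contribution(1, 2, m, emb), 2 * 1 / 1)
  expect_error(contribution(1, 1, m, emb), "void")
  expect_error(contribution(1, 2, toy_model(0), emb), "void")
})

test_that("contributions over U conserve the bag decision value exactly", {
  # the module's master correctness oracle, with the m^k factor on
  withr::with_seed(71, {
    for (trial in 1:100) {
      d <- random_dataset(n_bags = 4, n_bits = 8, max_inst = 5,
                          seed = 1000 + trial)
      nk <- sample(2:6, 1)
      ks <- sort(sample.int(n_instances(d), nk))
      emb <- build_embedding(ks, d)
      m <- toy_model(round(rnorm(nk), 2), intercept = rnorm(1))
      b <- sample.int(n_bags(d), 1)
      ic <- classify_instances(b, m, emb)
      lhs <- sum(ic$g[ic$U])
      rhs <- sum(m$weights[support(m)] * emb$values[support(m), b])
      expect_equal(lhs, rhs, tolerance = 1e-9)
    }
  })
  # with the factor off, the identity breaks when ties exist
  d <- mil_dataset(rbind(c(1, 1), c(1, 1)), c(1, 1), 1)
  emb <- build_embedding(restrict_concepts(mil_dataset(matrix(0, 1, 2), 1, 1), 1L), d)
  m <- toy_model(1)
  ic_off <- classify_instances(1, m, emb, use_mk_factor = FALSE)
  expect_equal(sum(ic_off$g[ic_off$U]), 2 * emb$values[1, 1])
})

test_that("instance classes replay the threshold definition", {
  fx2 <- figure1_fixture()
  emb <- build_embedding(fx2$concepts, fx2$dataset)
  # all-zero weights: everything void
  ic0 <- classify_instances(1, toy_model(numeric(5)), emb)
  expect_true(all(ic0$class == "void"))
  # auto threshold is -b/|U|
  m <- fx2$model; m$intercept <- 1.5
  ic <- classify_instances(1, m, emb, "auto")
  expect_equal(ic$threshold, -1.5 / 3)
  expect_equal(unname(as.character(ic$class)[3]), "void")
  expect_equal(ic$z[ic$U], ic$g[ic$U] > ic$threshold)
  # classification is invariant to concept reordering
  perm <- c(4L, 2L, 5L, 1L, 3L)
  cperm <- fx2$concepts
  cperm$bits <- cperm$bits[perm, ]
  cperm$concept_ids <- cperm$concept_ids[perm]
  cperm$source_label <- cperm$source_label[perm]
  mperm <- toy_model(m$weights[perm], m$intercept)
  icp <- classify_instances(1, mperm, build_embedding(cperm, fx2$dataset), "auto")
  expect_equal(icp$class, ic$class)
  expect_equal(icp$g, ic$g)
})

test_that("top-instance selection is gated, ranked, tie-broken and non-void", {
  gen <- small_planted(81, n_bags = 16, n_bits = 50, disc = 10)
  d <- gen$dataset
  emb <- build_embedding(seq_len(n_instances(d)), d)
  cv <- select_lambda(t(emb$values), d$bag_labels, folds = 4, seed = 81)
  m <- fit_one_norm(t(emb$values), d$bag_labels, cv$chosen_lambda)
  sel <- select_top_instances(d, m, emb, k_per_bag = 2)
  # labels match source-bag labels; no more than k per bag; none void
  expect_true(all(sel$y == d$bag_labels[sel$bag]))
  expect_true(all(table(sel$bag) <= 2))
  for (i in seq_along(sel$row)) {
    ic <- classify_instances(sel$bag[i], m, emb)
    local_idx <- match(sel$row[i], bag_rows(d, sel$bag[i]))
    expect_true(local_idx %in% ic$U)
  }
  # rows carry the original-feature-space bit-strings
  expect_equal(sel$X, d$instances[sel$row, , drop = FALSE])
})

test_that("selection enriches planted instances over the bag-level base rate", {
  hits <- vapply(1:5, function(s) {
    # rare planted instances (one in eight to ten) make the enrichment
    # ratio a sharp read-out of the ranking
    gen <- generate_planted(planted_params(
      n_pos_bags = 25, n_neg_bags = 25, instances_per_bag = c(8, 10),
      n_bits = 80, n_planted_patterns = 1, n_discriminative_bits = 12,
      positive_instances_per_pos_bag = c(1, 1),
      bit_flip_noise = 0.05, seed = 500 + s))
    d <- gen$dataset
    emb <- build_embedding(seq_len(n_instances(d)), d)
    cv <- select_lambda(t(emb$values), d$bag_labels, folds = 5, seed = 500 + s)
    m <- fit_one_norm(t(emb$values), d$bag_labels, cv$chosen_lambda)
    sel <- select_top_instances(d, m, emb, k_per_bag = 2)
    pos <- sel$row[sel$y > 0]
    base <- mean(gen$truth$is_planted[
      d$bag_of_row %in% which(d$bag_labels > 0)])
    mean(gen$truth$is_planted[pos]) / base
  }, numeric(1))
  expect_gte(median(hits), 3)
})

test_that("ties in g select the lower instance index first", {
  # two identical instances: identical g, tie broken by index
  d <- mil_dataset(rbind(c(0, 1), c(0, 1), c(1, 0)), c(1, 1, 1), 1)
  emb <- build_embedding(seq_len(3), d)
  m <- toy_model(c(-1, -1, -1), intercept = -3)
  sel <- select_top_instances(d, m, emb, k_per_bag = 1)
  expect_equal(sel$row, 1L)
})

test_that("single-instance bags: g equals the decision sum minus the intercept", {
  d <- mil_dataset(rbind(c(0, 1, 1), c(1, 0, 1)), c(1, 2), c(1, -1))
  emb <- build_embedding(seq_len(2), d)
  m <- toy_model(c(0.8, -0.6), intercept = 0.2)
  for (b in 1:2) {
    ic <- classify_instances(b, m, emb)
    expect_equal(sum(ic$g[ic$U]),
                 sum(m$weights * emb$values[, b]))
  }
})
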