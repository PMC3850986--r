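# Shared fixtures and independent oracles for the test suite.

# Random small MIL dataset, fully generic (no planted structure).
random_dataset <- function(n_bags = 10, n_bits = 12, max_inst = 4, seed = 1) {
  withr::with_seed(seed, {
    sizes <- sample.int(max_inst, n_bags, replace = TRUE)
    labels <- rep_len(c(1, -1), n_bags)
    bits <- matrix(rbinom(sum(sizes) * n_bits, 1, 0.5), ncol = n_bits)
    mil_dataset(bits, rep(seq_len(n_bags), sizes), labels)
  })
}

# Naive position-by-position Hamming loop (oracle for the BLAS route).
hamming_loop <- function(a, b) sum(as.integer(a) != as.integer(b))

# Independent LP oracle for the 1-norm hinge program, via boot::simplex
# (pure-R two-phase simplex). The innocuous A1 row (sum of variables
# bounded by a big constant) works around boot::simplex mishandling
# programs that have only >= constraints; it is slack at any optimum of
# this bounded-below program.
lp_oracle_objective <- function(X, y, lambda) {
  m <- nrow(X); p <- ncol(X)
  a <- c(rep(lambda, 2 * p), 0, 0, rep(1, m))
  A2 <- cbind(y * X, -y * X, y, -y, diag(m))
  s <- boot::simplex(a = a, A1 = matrix(1, 1, ncol(A2)), b1 = 1e6,
                     A2 = A2, b2 = rep(1, m), maxi = FALSE, n.iter = 10000)
  expect_equal(s$solved, 1)
  unname(s$value)
}

# A hand-built model over a given number of concepts (not fitted).
toy_model <- function(weights, intercept = 0) {
  structure(
    list(weights = as.numeric(weights), intercept = intercept,
         lambda = NA_real_, objective = NA_real_,
         support_tolerance = 1e-8 * max(1, max(abs(weights))),
         feature_ids = paste0("c", seq_along(weights))),
    class = "one_norm_fit")
}

# Small planted family for pipeline tests (scaled-down study conditions).
small_planted <- function(seed, n_bags = 20, n_bits = 60, disc = 10) {
  generate_planted(planted_params(
    n_pos_bags = n_bags / 2, n_neg_bags = n_bags / 2,
    instances_per_bag = c(3, 4), n_bits = n_bits,
    n_planted_patterns = 1, n_discriminative_bits = disc,
    positive_instances_per_pos_bag = c(1, 2),
    bit_flip_noise = 0.05, seed = seed))
}
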