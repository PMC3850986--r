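# Synthetic data: a hand-constructed worked example for instance
# classification, and a planted-concept generator for end-to-end
# simulation tests.

#' Worked toy example for instance classification
#'
#' One bag of four 6-bit instances and five concept targets with signs
#' (+, -, +, -, +), constructed so that, under Hamming distance, the
#' nearest-neighbor incidence is exactly: instance 1 is the nearest
#' neighbor of concepts 1 and 5 only; instance 2 of concepts 2 and 4 only;
#' instance 3 of no concept; instance 4 of concepts 2, 3 and 5 (ties
#' included). The multiplicities are therefore m = (1, 2, 1, 1, 2), the
#' responsible set is U = \{1, 2, 4\}, and with unit signed weights and
#' zero intercept instance 1 classifies positive, instance 2 negative,
#' instance 3 void (instance 4 sits exactly at the threshold and is
#' threshold-dependent). The incidence is re-derived from the raw
#' bit-strings at build time; a mismatch is an internal error.
#'
#' The incidence for instance 4 (concepts 2, 3, 5) is the unique
#' assignment consistent with all of the stated constraints: instance 4
#' neighbors both positive and negative concepts, instance 2 neighbors
#' only negative concepts, and the multiplicities are (1, 2, 1, 1, 2).
#'
#' @return List: \code{dataset} (a one-bag \code{mil_dataset}),
#'   \code{concepts} (a \code{mil_concepts}-style view with its own bits),
#'   \code{signs}, \code{model} (unit weights of those signs, zero
#'   intercept), \code{expected} (\code{incidence}, \code{U}, \code{mk},
#'   \code{classes}).
#' @export
figure1_fixture <- function() {
  inst <- c("110000", "001100", "000011", "111111")
  conc <- c("110000", "011101", "111111", "001100", "110110")
  signs <- c(1, -1, 1, -1, 1)
  bits <- do.call(rbind, lapply(inst, .as_bits))
  cbits <- do.call(rbind, lapply(conc, .as_bits))
  expected_incidence <- rbind(
    c(TRUE,  FALSE, FALSE, FALSE),   # concept 1 ~ instance 1
    c(FALSE, TRUE,  FALSE, TRUE),    # concept 2 ~ instances 2, 4
    c(FALSE, FALSE, FALSE, TRUE),    # concept 3 ~ instance 4
    c(FALSE, TRUE,  FALSE, FALSE),   # concept 4 ~ instance 2
    c(TRUE,  FALSE, FALSE, TRUE))    # concept 5 ~ instances 1, 4
  # self-check: replay the argmin scans from the raw bit-strings
  d <- hamming_cross(cbits, bits)
  inc <- d == apply(d, 1L, min)
  if (!identical(unname(inc), unname(expected_incidence)))
    stop("internal error: toy fixture bit-strings do not realize the intended incidence")
  dataset <- mil_dataset(bits, rep(1L, 4L), bag_labels = 1,
                         bag_ids = "toy",
                         instance_ids = paste0("x", 1:4))
  concepts <- structure(
    list(bits = cbits, source_row = NA_integer_,
         source_bag = NA_integer_, source_label = signs,
         concept_ids = paste0("c", 1:5),
         feature_ids = dataset$feature_ids),
    class = "mil_concepts")
  model <- structure(
    list(weights = as.numeric(signs), intercept = 0, lambda = NA_real_,
         objective = NA_real_, support_tolerance = 1e-8,
         feature_ids = concepts$concept_ids),
    class = "one_norm_fit")
  list(dataset = dataset, concepts = concepts, signs = signs,
       model = model,
       expected = list(incidence = expected_incidence,
                       U = c(1L, 2L, 4L),
                       mk = c(1L, 2L, 1L, 1L, 2L),
                       classes = c("positive", "negative", "void")))
}

#' Parameters of the planted-concept generator
#'
#' Defaults emulate, at desk scale, fingerprint datasets of a few hundred
#' molecules with a handful of conformers each and a 500-bit fingerprint in
#' which a small set of bits carries the activity signal: positive bags
#' contain one or two instances drawn from one of a few planted "bioactive"
#' bit patterns (signature on the discriminative bits, then bit-flip
#' noise), all other instances and all negative-bag instances are pure
#' background (each bit Bernoulli(0.5)).
#'
#' @param n_pos_bags,n_neg_bags bag counts (default 100 + 100).
#' @param instances_per_bag inclusive integer range, default \code{c(4, 6)}.
#' @param n_bits fingerprint length, default 500.
#' @param n_planted_patterns number of distinct bioactive patterns, default 2.
#' @param n_discriminative_bits signature length, default 20.
#' @param positive_instances_per_pos_bag inclusive range, default \code{c(1, 2)}.
#' @param bit_flip_noise per-bit flip probability on planted signatures,
#'   in [0, 0.5], default 0.05.
#' @param seed integer seed.
#' @return A validated parameter list of class \code{"planted_params"}.
#' @export
planted_params <- function(n_pos_bags = 100, n_neg_bags = 100,
                           instances_per_bag = c(4, 6),
                           n_bits = 500, n_planted_patterns = 2,
                           n_discriminative_bits = 20,
                           positive_instances_per_pos_bag = c(1, 2),
                           bit_flip_noise = 0.05, seed = 1) {
  p <- list(n_pos_bags = as.integer(n_pos_bags),
            n_neg_bags = as.integer(n_neg_bags),
            instances_per_bag = as.integer(rep_len(instances_per_bag, 2L)),
            n_bits = as.integer(n_bits),
            n_planted_patterns = as.integer(n_planted_patterns),
            n_discriminative_bits = as.integer(n_discriminative_bits),
            positive_instances_per_pos_bag =
              as.integer(rep_len(positive_instances_per_pos_bag, 2L)),
            bit_flip_noise = as.numeric(bit_flip_noise),
            seed = as.integer(seed))
  stopifnot(p$n_pos_bags >= 1L, p$n_neg_bags >= 1L, p$n_bits >= 1L,
            p$n_planted_patterns >= 1L,
            p$n_discriminative_bits >= 1L,
            p$n_discriminative_bits <= p$n_bits,
            p$instances_per_bag[1L] >= 1L,
            p$instances_per_bag[2L] >= p$instances_per_bag[1L],
            p$positive_instances_per_pos_bag[1L] >= 1L,
            p$bit_flip_noise >= 0, p$bit_flip_noise <= 0.5)
  if (p$positive_instances_per_pos_bag[2L] > p$instances_per_bag[1L])
    stop("infeasible counts: a positive bag could need more planted instances than it has room for")
  structure(p, class = "planted_params")
}

#' Generate a planted-concept multiple-instance dataset
#'
#' See \code{\link{planted_params}} for the generative model. Planted
#' instances are inserted at random positions within their bag, so
#' position within a bag leaks no label information. Deterministic given
#' the seed.
#'
#' @param params a \code{\link{planted_params}} list.
#' @return List with \code{dataset} (a \code{mil_dataset}) and
#'   \code{truth}: \code{is_planted} (per instance row),
#'   \code{pattern_id} (NA for background), \code{discriminative_bits}
#'   (bit indices), \code{patterns} (pattern-by-signature 0/1 matrix).
#' @export
generate_planted <- function(params = planted_params()) {
  stopifnot(inherits(params, "planted_params"))
  p <- params
  with_seed(p$seed, {
    disc <- sort(sample.int(p$n_bits, p$n_discriminative_bits))
    patterns <- matrix(rbinom(p$n_planted_patterns * p$n_discriminative_bits,
                              1L, 0.5),
                       nrow = p$n_planted_patterns)
    n_b <- p$n_pos_bags + p$n_neg_bags
    labels <- rep(c(1, -1), c(p$n_pos_bags, p$n_neg_bags))
    size_range <- seq(p$instances_per_bag[1L], p$instances_per_bag[2L])
    sizes <- size_range[sample.int(length(size_range), n_b, replace = TRUE)]
    n <- sum(sizes)
    bits <- matrix(rbinom(n * p$n_bits, 1L, 0.5), nrow = n)
    is_planted <- logical(n)
    pattern_id <- rep(NA_integer_, n)
    offset <- 0L
    for (b in seq_len(n_b)) {
      if (labels[b] > 0) {
        k_range <- seq(p$positive_instances_per_pos_bag[1L],
                       min(p$positive_instances_per_pos_bag[2L], sizes[b]))
        k <- k_range[sample.int(length(k_range), 1L)]
        slots <- offset + sample.int(sizes[b], k)
        for (r in slots) {
          pat <- sample.int(p$n_planted_patterns, 1L)
          sig <- patterns[pat, ]
          flips <- rbinom(p$n_discriminative_bits, 1L, p$bit_flip_noise)
          bits[r, disc] <- as.integer(xor(sig, flips))
          is_planted[r] <- TRUE
          pattern_id[r] <- pat
        }
      }
      offset <- offset + sizes[b]
    }
    dataset <- mil_dataset(bits, rep(seq_len(n_b), sizes), labels)
    list(dataset = dataset,
         truth = list(is_planted = is_planted, pattern_id = pattern_id,
                      discriminative_bits = disc, patterns = patterns))
  })
}

#' Stratified bag-level train/test split
#'
#' @param d a \code{mil_dataset}.
#' @param ratio training fraction in (0, 1); the study protocol here uses
#'   roughly 3:1, i.e. \code{ratio = 0.75}.
#' @param seed integer seed.
#' @return List with \code{train} and \code{test} datasets (disjoint bags,
#'   union the input, both classes present in both parts).
#' @export
split_train_test <- function(d, ratio = 0.75, seed = 1) {
  stopifnot(inherits(d, "mil_dataset"), ratio > 0, ratio < 1)
  # per-class training quotas by largest remainder, so the overall train
  # size is round(ratio * n_bags) while staying stratified
  cls <- lapply(c(1, -1), function(cl) which(d$bag_labels == cl))
  quota <- vapply(cls, length, integer(1)) * ratio
  k <- floor(quota)
  short <- round(ratio * n_bags(d)) - sum(k)
  if (short > 0) {
    bump <- order(quota - k, decreasing = TRUE)[seq_len(short)]
    k[bump] <- k[bump] + 1L
  }
  if (any(k < 1L) || any(k >= lengths(cls)))
    stop("a class would be empty in the train or test part")
  train_bags <- with_seed(seed, {
    unlist(mapply(function(idx, ki) sample(idx, ki), cls, k,
                  SIMPLIFY = FALSE))
  })
  list(train = .subset_bags(d, sort(train_bags)),
       test = .subset_bags(d, sort(setdiff(seq_len(n_bags(d)), train_bags))))
}

.subset_bags <- function(d, bags) {
  rows <- unlist(bag_row_list(d)[bags], use.names = FALSE)
  mil_dataset(d$instances[rows, , drop = FALSE],
              match(d$bag_of_row[rows], bags),
              d$bag_labels[bags], d$bag_ids[bags],
              d$instance_ids[rows], d$feature_ids)
}
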