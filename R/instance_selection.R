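# Classification of the instances inside a bag by their contribution to
# the bag's decision value, and selection of top-ranked instances for the
# second-stage fit in the original fingerprint space.

# support-restricted quantities shared by the operations below
.bag_support_state <- function(bag, model, emb) {
  i <- support(model)
  inc <- if (length(i) > 0L)
    nearest_incidence(emb, bag)[i, , drop = FALSE]
  else matrix(FALSE, 0L, length(emb$bag_rows[[bag]]))
  list(I = i, inc = inc, mk = rowSums(inc))
}

#' Responsible set of a bag
#'
#' The minimal set U of a bag's instances that carries the bag's decision
#' value: the union, over the support concepts, of the instances tied as
#' nearest neighbors of each concept. Instances outside U belong to the
#' void class and can be dropped from the decision rule without changing
#' it. With empty support, U is empty and the bag is classified by the
#' intercept alone.
#'
#' @param bag bag index.
#' @param model a \code{\link{fit_one_norm}} fit over the embedding's
#'   concepts.
#' @param emb the \code{\link{build_embedding}} of the bag's dataset.
#' @return Sorted bag-local instance indices.
#' @export
responsible_set <- function(bag, model, emb) {
  st <- .bag_support_state(bag, model, emb)
  which(colSums(st$inc) > 0L)
}

#' Concept-to-instance assignments and multiplicities within a bag
#'
#' For each responsible instance j*, the set I_j* of support concepts for
#' which j* is a nearest neighbor; for each support concept k, the
#' multiplicity m^k = number of the bag's instances tied as its nearest
#' neighbors (always >= 1: the minimum is attained in the bag).
#'
#' @inheritParams responsible_set
#' @return List with \code{U}, \code{assigned} (per instance in U, the
#'   support concept indices), \code{mk} (named by support concept index).
#' @export
concept_assignments <- function(bag, model, emb) {
  st <- .bag_support_state(bag, model, emb)
  u <- which(colSums(st$inc) > 0L)
  assigned <- lapply(u, function(j) st$I[st$inc[, j]])
  names(assigned) <- u
  mk <- st$mk
  names(mk) <- st$I
  list(U = u, assigned = assigned, mk = mk)
}

#' Contribution of one instance to its bag's decision value
#'
#' \deqn{g(x_{ij^*}) = \sum_{k \in I_{j^*}} w_k \, s(x^k, x_{ij^*}) / m^k,}
#' where s is the pointwise similarity between the concept and the
#' instance (for the min-distance mapping this equals the bag-level cell,
#' since j* is a minimizer). Dividing by the multiplicity m^k shares each
#' concept's contribution among its tied nearest neighbors, so that the
#' contributions over U sum exactly to the bag's decision value (minus the
#' intercept). The divisor can be disabled, in which case the conservation
#' identity fails whenever ties exist.
#'
#' @inheritParams responsible_set
#' @param instance bag-local index of a responsible instance.
#' @param use_mk_factor divide by m^k (default TRUE).
#' @return The contribution g, a real number.
#' @export
contribution <- function(bag, instance, model, emb, use_mk_factor = TRUE) {
  st <- .bag_support_state(bag, model, emb)
  if (instance < 1L || instance > ncol(st$inc) ||
      !any(st$inc[, instance]))
    stop("instance ", instance, " is void (not in the responsible set) or out of range")
  ks <- which(st$inc[, instance])
  pw <- emb$pointwise[st$I[ks], emb$bag_rows[[bag]][instance]]
  div <- if (use_mk_factor) st$mk[ks] else 1
  sum(model$weights[st$I[ks]] * pw / div)
}

#' Classify the instances of a bag as positive, negative or void
#'
#' Instances outside the responsible set are void. A responsible instance
#' is positive when its contribution g exceeds the threshold, negative
#' otherwise. In \code{auto} mode the threshold is -b/|U| (each
#' responsible instance is compared against its equal share of the
#' negated intercept); in \code{fixed} mode it is supplied by the caller.
#'
#' @inheritParams responsible_set
#' @param threshold_mode \code{"auto"} or \code{"fixed"}.
#' @param threshold the fixed threshold (ignored in auto mode).
#' @param use_mk_factor see \code{\link{contribution}}.
#' @return Object of class \code{"instance_classification"}: per-instance
#'   \code{class} (factor positive/negative/void), \code{g} (NA for void),
#'   \code{z} (g > threshold), plus \code{U}, \code{mk}, \code{assigned},
#'   \code{threshold}.
#' @export
classify_instances <- function(bag, model, emb,
                               threshold_mode = c("auto", "fixed"),
                               threshold = 0, use_mk_factor = TRUE) {
  threshold_mode <- match.arg(threshold_mode)
  st <- .bag_support_state(bag, model, emb)
  n_i <- length(emb$bag_rows[[bag]])
  u <- which(colSums(st$inc) > 0L)
  g <- rep(NA_real_, n_i)
  if (length(u) > 0L) {
    div <- if (use_mk_factor) st$mk else rep(1, length(st$mk))
    wk <- model$weights[st$I] / div
    pw <- emb$pointwise[st$I, emb$bag_rows[[bag]], drop = FALSE]
    g[u] <- colSums((st$inc * pw)[, u, drop = FALSE] * wk)
  }
  delta <- if (threshold_mode == "auto") {
    if (length(u) == 0L) NA_real_ else -model$intercept / length(u)
  } else threshold
  z <- !is.na(g) & !is.na(delta) & g > delta
  cls <- rep("void", n_i)
  cls[u] <- ifelse(z[u], "positive", "negative")
  assigned <- lapply(u, function(j) st$I[st$inc[, j]])
  names(assigned) <- u
  mk <- st$mk; names(mk) <- st$I
  structure(
    list(bag = bag, class = factor(cls, c("positive", "negative", "void")),
         g = g, z = z, U = u, mk = mk, assigned = assigned,
         threshold = delta),
    class = "instance_classification")
}

#' @export
print.instance_classification <- function(x, ...) {
  cat(sprintf("bag %d: %s (threshold %.4g)\n", x$bag,
              paste(sprintf("%d instances %s", table(x$class),
                            levels(x$class)), collapse = ", "),
              x$threshold))
  invisible(x)
}

#' Select top-ranked instances per bag for the second-stage fit
#'
#' From each positive bag, the \code{k_per_bag} responsible instances
#' ranked highest as evidence for the bag's label, labeled +1 and gated by
#' the decision threshold; from each negative bag, the \code{k_per_bag}
#' instances ranked highest as evidence for the negative label (no gate),
#' labeled -1. Bags with fewer eligible instances contribute all they
#' have. Ties in g break toward the lower instance index. The returned
#' rows carry the bit-strings of the dataset the embedding was built on
#' (i.e. the current feature subspace).
#'
#' The ranking direction follows the orientation of the similarity. Under
#' a genuine similarity (\code{gaussian_max}), concepts characteristic of
#' positive bags carry positive weights, so instances with the
#' \emph{largest} g are the positive evidence and the gate keeps
#' \code{g > threshold}. Under the min-distance mapping, s is a
#' dissimilarity and the classifier's weights reorient: concepts
#' characteristic of positive bags carry \emph{negative} weights, the
#' instances nearest them have the most \emph{negative} g, and the whole
#' ranking reverses (gate \code{g < threshold}, ascending g from positive
#' bags, descending from negative ones). Applying the similarity-oriented
#' rule to the dissimilarity mapping would systematically select the
#' instances that argue \emph{against} their bag's label.
#'
#' The \code{"ascending"} rule instead sorts the gated g ascending in
#' every bag and takes the first k; it is kept for auditability against
#' the pseudocode convention.
#'
#' @param d the \code{mil_dataset} the embedding was built on.
#' @param model,emb as in \code{\link{responsible_set}}.
#' @param k_per_bag instances to take from each bag (default 2).
#' @param use_mk_factor see \code{\link{contribution}}.
#' @param rule \code{"by_label"} (default) or \code{"ascending"}.
#' @return List with \code{X} (selected instances x bits), \code{y}
#'   (+1/-1), \code{bag} (source bag), \code{row} (source instance row).
#' @export
select_top_instances <- function(d, model, emb, k_per_bag = 2,
                                 use_mk_factor = TRUE,
                                 rule = c("by_label", "ascending")) {
  rule <- match.arg(rule)
  if (k_per_bag < 1L) stop("k_per_bag must be at least 1")
  rows <- integer(); labs <- numeric(); bags <- integer()
  for (b in seq_len(n_bags(d))) {
    ic <- classify_instances(b, model, emb, "auto",
                             use_mk_factor = use_mk_factor)
    if (length(ic$U) == 0L) next
    lab <- d$bag_labels[b]
    # +1: larger g = positive evidence (similarity); -1: reversed
    # (dissimilarity: discriminative concepts carry negative weights)
    orient <- if (emb$similarity_kind == "min_distance") -1 else 1
    cand <- if (rule == "ascending") {
      ic$U[order(ifelse(ic$z[ic$U], ic$g[ic$U], 0), ic$U)]
    } else if (lab > 0) {
      el <- ic$U[orient * ic$g[ic$U] > orient * ic$threshold]
      el[order(-orient * ic$g[el], el)]
    } else {
      ic$U[order(orient * ic$g[ic$U], ic$U)]
    }
    take <- head(cand, k_per_bag)
    rows <- c(rows, emb$bag_rows[[b]][take])
    labs <- c(labs, rep(lab, length(take)))
    bags <- c(bags, rep(b, length(take)))
  }
  if (length(rows) == 0L)
    stop("no eligible instances anywhere: degenerate model (empty selection)")
  list(X = d$instances[rows, , drop = FALSE], y = labs,
       bag = bags, row = rows)
}

#' Write a per-instance classification report as TSV
#'
#' One row per instance of the dataset: bag id, instance id, class, g, z,
#' and the assigned concept ids.
#'
#' @param d dataset; \code{model}, \code{emb} as above.
#' @param model,emb fitted model and embedding.
#' @param path file to write.
#' @param use_mk_factor see \code{\link{contribution}}.
#' @export
write_instance_report <- function(d, model, emb, path, use_mk_factor = TRUE) {
  out <- lapply(seq_len(n_bags(d)), function(b) {
    ic <- classify_instances(b, model, emb, "auto",
                             use_mk_factor = use_mk_factor)
    rows <- emb$bag_rows[[b]]
    data.frame(
      bag_id = d$bag_ids[b], instance_id = d$instance_ids[rows],
      class = as.character(ic$class),
      g = ic$g, z = ic$z,
      assigned_concept_ids = vapply(seq_along(rows), function(j) {
        a <- ic$assigned[[as.character(j)]]
        if (is.null(a)) "" else paste(emb$concept_ids[a], collapse = ",")
      }, character(1)),
      stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, out), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
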