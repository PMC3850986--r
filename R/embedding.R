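#' Hamming distance between two binary vectors
#'
#' Number of differing positions. Used as the dissimilarity between
#' pharmacophore fingerprints.
#'
#' @param a,b 0/1 vectors of equal length, or strings over \{0,1\}.
#' @return Non-negative integer.
#' @examples
#' hamming_distance("0101", "1010")
#' @export
hamming_distance <- function(a, b) {
  a <- .as_bits(a); b <- .as_bits(b)
  if (length(a) != length(b)) stop("bit-vector length mismatch")
  sum(a != b)
}

.as_bits <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    v <- utf8ToInt(x) - utf8ToInt("0")
    if (any(v != 0L & v != 1L)) stop("malformed bit-string")
    return(v)
  }
  x <- as.integer(x)
  if (any(x != 0L & x != 1L)) stop("bit-vector entries must be 0 or 1")
  x
}

#' Minimum-distance similarity between a concept target and a bag
#'
#' The similarity used in the experiments is the plain minimum over the
#' bag's instances of the Hamming distance to the concept target. It is a
#' dissimilarity (small means similar); it is deliberately not negated or
#' inverted — the signed weights of the linear classifier absorb the
#' orientation. All minimizing instances are reported, since downstream
#' multiplicity counts treat every tied instance as a nearest neighbor.
#'
#' @param concept a 0/1 vector or bit-string.
#' @param bag matrix of 0/1 instance rows (non-empty).
#' @return List with \code{value} (the minimum distance) and \code{argmin}
#'   (indices of all instances attaining it).
#' @export
similarity_min_distance <- function(concept, bag) {
  concept <- .as_bits(concept)
  bag <- as.matrix(bag)
  if (nrow(bag) < 1L) stop("bag must contain at least one instance")
  if (ncol(bag) != length(concept)) stop("bit-vector length mismatch")
  d <- as.vector(hamming_cross(matrix(concept, nrow = 1L), bag))
  list(value = min(d), argmin = which(d == min(d)))
}

#' Gaussian-kernel maximum similarity between a concept target and a bag
#'
#' \code{max_j exp(-||x_ij - x^k||^2 / sigma^2)}, with the squared norm of
#' 0/1 vectors equal to their Hamming distance. Values lie in (0, 1]; 1 iff
#' the bag contains the concept exactly.
#'
#' @inheritParams similarity_min_distance
#' @param sigma positive kernel width.
#' @return List with \code{value} and \code{argmax} (all maximizing
#'   instances).
#' @export
similarity_gaussian_max <- function(concept, bag, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a positive number")
  concept <- .as_bits(concept)
  bag <- as.matrix(bag)
  if (nrow(bag) < 1L) stop("bag must contain at least one instance")
  if (ncol(bag) != length(concept)) stop("bit-vector length mismatch")
  d <- as.vector(hamming_cross(matrix(concept, nrow = 1L), bag))
  s <- exp(-d / sigma^2)
  list(value = max(s), argmax = which(s == max(s)))
}

#' Embed bags into the instance-based feature space
#'
#' Builds the concept-by-bag similarity matrix M: rows are concept targets
#' (training instances), columns are bags, cell (k, i) the similarity
#' between concept k and bag i under the chosen mapping. With
#' \code{min_distance}, the per-instance Hamming distances are retained so
#' that nearest-neighbor (argmin) sets, including ties, are available to
#' the instance-classification step.
#'
#' @param concepts a \code{\link{restrict_concepts}} view, or an integer
#'   vector of instance-row indices resolved against \code{d}. At test
#'   time pass the concept view taken from the \emph{training} data.
#' @param d the \code{mil_dataset} whose bags are embedded.
#' @param kind \code{"min_distance"} (default; Hamming) or
#'   \code{"gaussian_max"}.
#' @param sigma kernel width, used only by \code{gaussian_max}.
#' @return Object of class \code{"mil_embedding"}: \code{values}
#'   (n_concepts x n_bags), \code{pointwise} (n_concepts x n_instances
#'   per-instance similarities: raw distances for \code{min_distance},
#'   kernel values for \code{gaussian_max}), ids, bag structure, kind,
#'   sigma.
#' @export
build_embedding <- function(concepts, d, kind = c("min_distance", "gaussian_max"),
                            sigma = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(d, "mil_dataset"))
  if (!inherits(concepts, "mil_concepts"))
    concepts <- restrict_concepts(d, concepts)
  if (ncol(concepts$bits) != ncol(d$instances))
    stop("concepts and dataset do not share a feature space")
  pw <- hamming_cross(concepts$bits, d$instances)
  if (kind == "gaussian_max") {
    if (sigma <= 0) stop("sigma must be a positive number")
    pw <- exp(-pw / sigma^2)
  }
  rows <- bag_row_list(d)
  values <- matrix(NA_real_, nrow(pw), length(rows))
  for (b in seq_along(rows)) {
    cols <- rows[[b]]
    m <- pw[, cols[1L]]
    if (length(cols) > 1L) for (j in cols[-1L])
      m <- if (kind == "min_distance") pmin(m, pw[, j]) else pmax(m, pw[, j])
    values[, b] <- m
  }
  structure(
    list(values = values, pointwise = pw,
         concept_ids = concepts$concept_ids, bag_ids = d$bag_ids,
         bag_rows = rows, similarity_kind = kind,
         sigma = if (kind == "gaussian_max") sigma else NA_real_),
    class = "mil_embedding")
}

#' @export
print.mil_embedding <- function(x, ...) {
  cat(sprintf("instance-embedded mapping: %d concepts x %d bags (%s)\n",
              nrow(x$values), ncol(x$values), x$similarity_kind))
  invisible(x)
}

# Per-bag nearest-neighbor incidence: logical n_concepts x n_i matrix,
# TRUE where the instance attains the bag's extremal similarity for that
# concept (all ties included). Exact comparison is safe for min_distance
# (integer distances); gaussian values are compared within 1e-12.
nearest_incidence <- function(emb, bag) {
  cols <- emb$bag_rows[[bag]]
  pw <- emb$pointwise[, cols, drop = FALSE]
  v <- emb$values[, bag]
  if (emb$similarity_kind == "min_distance") pw == v
  else abs(pw - v) < 1e-12
}

#' Nearest instances of each concept within one bag
#'
#' For the \code{min_distance} mapping, the set of instances of \code{bag}
#' attaining the minimum distance to each concept (argmin ties all
#' retained); for \code{gaussian_max}, the argmax set.
#'
#' @param emb a \code{mil_embedding}.
#' @param bag bag index.
#' @return List, one integer vector of bag-local instance indices per
#'   concept.
#' @export
nearest_instances <- function(emb, bag) {
  inc <- nearest_incidence(emb, bag)
  lapply(seq_len(nrow(inc)), function(k) which(inc[k, ]))
}

#' Export an embedding matrix as TSV for inspection
#' @param emb a \code{mil_embedding}.
#' @param path file to write.
#' @export
write_embedding_tsv <- function(emb, path) {
  m <- emb$values
  dimnames(m) <- list(emb$concept_ids, emb$bag_ids)
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(NULL)
}
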