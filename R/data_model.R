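#' Construct a multiple-instance dataset of binary fingerprints
#'
#' A MIL dataset is a set of labeled bags (e.g. molecules), each holding one
#' or more instances (e.g. conformers) represented as fixed-length binary
#' bit-vectors (e.g. pharmacophore fingerprints). Instances of all bags are
#' lined up and re-indexed into a single dense 0/1 matrix, row-contiguous
#' per bag; bag membership is kept in an index vector. Bag labels are +1
#' (positive/active) or -1 (negative/inactive).
#'
#' @param instances integer or numeric matrix of 0/1 values, one instance
#'   per row, one fingerprint bit per column. Rows of a bag must be
#'   contiguous.
#' @param bag_of_row integer vector, length \code{nrow(instances)}: for each
#'   instance row, the (1-based) index of the bag it belongs to. Must be
#'   non-decreasing and cover \code{1..n_bags} without gaps.
#' @param bag_labels numeric vector of +1/-1, one per bag.
#' @param bag_ids,instance_ids,feature_ids optional character identifiers;
#'   defaults are generated. \code{feature_ids} must be unique.
#' @return An object of class \code{"mil_dataset"} with components
#'   \code{instances}, \code{bag_of_row}, \code{bag_labels}, \code{bag_ids},
#'   \code{instance_ids}, \code{feature_ids}.
#' @examples
#' d <- mil_dataset(rbind(c(0,1,0,1), c(0,1,1,0), c(1,0,1,0)),
#'                  bag_of_row = c(1, 1, 2), bag_labels = c(1, -1))
#' n_bags(d)
#' @export
mil_dataset <- function(instances, bag_of_row, bag_labels,
                        bag_ids = NULL, instance_ids = NULL,
                        feature_ids = NULL) {
  instances <- as.matrix(instances)
  storage.mode(instances) <- "integer"
  if (ncol(instances) < 1L) stop("dataset must have at least one fingerprint bit")
  if (!all(instances %in% c(0L, 1L)))
    stop("instance matrix entries must all be 0 or 1")
  bag_of_row <- as.integer(bag_of_row)
  if (length(bag_of_row) != nrow(instances))
    stop("bag_of_row must have one entry per instance row")
  if (is.unsorted(bag_of_row))
    stop("instances of a bag must occupy contiguous rows (bag_of_row non-decreasing)")
  n_bags <- length(bag_labels)
  if (n_bags < 1L) stop("dataset must contain at least one bag")
  if (!setequal(unique(bag_of_row), seq_len(n_bags)))
    stop("every bag must have at least one instance and bag indices must be 1..n_bags")
  bag_labels <- as.numeric(bag_labels)
  if (!all(bag_labels %in% c(-1, 1)))
    stop("bag labels must be +1 or -1")
  bag_ids <- as.character(bag_ids %||% paste0("bag", seq_len(n_bags)))
  if (anyDuplicated(bag_ids)) stop("duplicate bag id")
  if (length(bag_ids) != n_bags) stop("bag_ids length mismatch")
  instance_ids <- as.character(instance_ids %||% paste0("inst", seq_len(nrow(instances))))
  if (anyDuplicated(instance_ids)) stop("duplicate instance id")
  if (length(instance_ids) != nrow(instances)) stop("instance_ids length mismatch")
  feature_ids <- as.character(feature_ids %||% paste0("bit", seq_len(ncol(instances))))
  if (anyDuplicated(feature_ids)) stop("duplicate feature id")
  if (length(feature_ids) != ncol(instances)) stop("feature_ids length mismatch")
  structure(
    list(instances = instances, bag_of_row = bag_of_row,
         bag_labels = bag_labels, bag_ids = bag_ids,
         instance_ids = instance_ids, feature_ids = feature_ids),
    class = "mil_dataset")
}

#' @export
print.mil_dataset <- function(x, ...) {
  cat(sprintf("MIL dataset: %d bags (%d positive, %d negative), %d instances, %d bits\n",
              n_bags(x), sum(x$bag_labels > 0), sum(x$bag_labels < 0),
              nrow(x$instances), ncol(x$instances)))
  invisible(x)
}

#' Numbers of bags, instances and fingerprint bits
#' @param d a \code{mil_dataset}.
#' @return An integer count.
#' @export
n_bags <- function(d) length(d$bag_labels)

#' @rdname n_bags
#' @export
n_instances <- function(d) nrow(d$instances)

#' @rdname n_bags
#' @export
n_bits <- function(d) ncol(d$instances)

#' Row indices of the instances of one bag
#' @param d a \code{mil_dataset}.
#' @param bag bag index (1-based).
#' @return Integer vector of instance-row indices, contiguous.
#' @export
bag_rows <- function(d, bag) which(d$bag_of_row == bag)

# list of row-index vectors, one per bag
bag_row_list <- function(d) split(seq_len(nrow(d$instances)), d$bag_of_row)

#' Restrict a dataset to a subset of fingerprint bits
#'
#' Returns a dataset whose instance matrix keeps only the selected columns,
#' in the order given. Bag structure is unchanged. This is the feature
#' elimination step of the selection loop: the surviving feature set indexes
#' the original fingerprint space.
#'
#' @param d a \code{mil_dataset}.
#' @param features integer vector of column indices (unique, within range).
#' @return A \code{mil_dataset} on the restricted bit space.
#' @export
restrict_features <- function(d, features) {
  features <- as.integer(features)
  if (length(features) < 1L) stop("feature subset must be non-empty")
  if (anyDuplicated(features)) stop("feature subset contains duplicates")
  if (any(features < 1L | features > ncol(d$instances)))
    stop("feature index out of range")
  mil_dataset(d$instances[, features, drop = FALSE], d$bag_of_row,
              d$bag_labels, d$bag_ids, d$instance_ids,
              d$feature_ids[features])
}

#' Select concept targets (a view on instance rows)
#'
#' A concept target is a training instance regarded as one axis of the
#' instance-embedded space. Selecting concepts never reduces the bags
#' themselves: all bags keep all their instances for the mapping; only the
#' set of rows used as embedding axes shrinks. Concept identity is
#' positional — duplicate bit-patterns are retained as distinct concepts.
#'
#' @param d a \code{mil_dataset}.
#' @param concepts integer vector of instance-row indices (unique, in range).
#' @return An object of class \code{"mil_concepts"}: \code{bits} (the
#'   concept rows), \code{source_row}, \code{source_bag},
#'   \code{source_label}, \code{concept_ids}, \code{feature_ids}.
#' @export
restrict_concepts <- function(d, concepts) {
  concepts <- as.integer(concepts)
  if (length(concepts) < 1L) stop("concept subset must be non-empty")
  if (anyDuplicated(concepts)) stop("concept subset contains duplicates")
  if (any(concepts < 1L | concepts > nrow(d$instances)))
    stop("concept index out of range")
  structure(
    list(bits = d$instances[concepts, , drop = FALSE],
         source_row = concepts,
         source_bag = d$bag_of_row[concepts],
         source_label = d$bag_labels[d$bag_of_row[concepts]],
         concept_ids = d$instance_ids[concepts],
         feature_ids = d$feature_ids),
    class = "mil_concepts")
}

#' @export
print.mil_concepts <- function(x, ...) {
  cat(sprintf("%d concept targets over %d bits (%d from positive bags)\n",
              nrow(x$bits), ncol(x$bits), sum(x$source_label > 0)))
  invisible(x)
}
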