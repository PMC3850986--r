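# Readers and writers for the bag/instance TSV and JSON dialects.

# Label tokens accepted on input. Note "0" means negative: common
# fingerprint exports use 0/1 activity labels.
.parse_label <- function(tok, where) {
  if (tok %in% c("1", "+1", "pos")) return(1)
  if (tok %in% c("-1", "0", "neg")) return(-1)
  stop(sprintf("unknown bag label token '%s' at %s", tok, where))
}

.parse_bits <- function(s, n_bits, where) {
  if (is.na(n_bits)) n_bits <- nchar(s)
  if (nchar(s) != n_bits)
    stop(sprintf("bit-string of length %d (expected %d) at %s",
                 nchar(s), n_bits, where))
  v <- utf8ToInt(s) - utf8ToInt("0")
  if (any(v != 0L & v != 1L))
    stop(sprintf("malformed bit-string (non-0/1 character) at %s", where))
  v
}

#' Read a multiple-instance dataset from TSV or JSON
#'
#' The TSV dialect has one instance per line,
#' \code{bag_id<TAB>bag_label<TAB>instance_id<TAB>bitstring}, a mandatory
#' header line, and \code{#} comment lines. Labels may be written
#' \code{1/+1/pos} or \code{-1/0/neg} (so \code{0} is negative). The JSON
#' dialect is an object with \code{n_bits} and \code{bags}, each bag
#' \code{\{id, label, instances: [\{id, bits\}]\}}. Instance order within a
#' bag follows file order.
#'
#' @param path file to read.
#' @param format \code{"tsv"} or \code{"json"}; default guessed from the
#'   file extension.
#' @return A validated \code{\link{mil_dataset}}.
#' @export
read_mil <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "json") .read_mil_json(path) else .read_mil_tsv(path)
}

.read_mil_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) < 2L)
    stop("empty dataset file (need a header line and at least one instance): ", path)
  header <- strsplit(lines[keep[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 4L ||
      !identical(tolower(header[1:4]),
                 c("bag_id", "bag_label", "instance_id", "bitstring")))
    stop("bad TSV header (expected bag_id, bag_label, instance_id, bitstring): ", path)
  body <- keep[-1L]
  recs <- strsplit(lines[body], "\t", fixed = TRUE)
  n_bits <- NA_integer_
  bag_ids <- character(); bag_labels <- numeric()
  bag_of_row <- integer(); instance_ids <- character()
  bits <- vector("list", length(body))
  for (i in seq_along(body)) {
    where <- sprintf("line %d of %s", body[i], path)
    f <- recs[[i]]
    if (length(f) != 4L) stop("expected 4 tab-separated fields at ", where)
    bag <- match(f[1L], bag_ids)
    lab <- .parse_label(f[2L], where)
    if (is.na(bag)) {
      bag_ids <- c(bag_ids, f[1L]); bag_labels <- c(bag_labels, lab)
      bag <- length(bag_ids)
    } else {
      if (bag_labels[bag] != lab)
        stop("inconsistent label for bag '", f[1L], "' at ", where)
      if (bag != bag_of_row[length(bag_of_row)])
        stop("instances of bag '", f[1L], "' are not contiguous at ", where)
    }
    bits[[i]] <- .parse_bits(f[4L], n_bits, where)
    n_bits <- length(bits[[i]])
    bag_of_row <- c(bag_of_row, bag)
    instance_ids <- c(instance_ids, f[3L])
  }
  if (anyDuplicated(instance_ids)) stop("duplicate instance id in ", path)
  mil_dataset(do.call(rbind, bits), bag_of_row, bag_labels,
              bag_ids, instance_ids)
}

.read_mil_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$bags) || length(obj$bags) == 0L)
    stop("empty dataset file (no bags): ", path)
  n_bits <- obj$n_bits %||% NA_integer_
  bits <- list(); bag_of_row <- integer()
  bag_ids <- character(); bag_labels <- numeric(); instance_ids <- character()
  for (b in seq_along(obj$bags)) {
    bag <- obj$bags[[b]]
    where <- sprintf("bag %d of %s", b, path)
    if (is.null(bag$instances) || length(bag$instances) == 0L)
      stop("bag with zero instances at ", where)
    bag_ids <- c(bag_ids, as.character(bag$id %||% paste0("bag", b)))
    bag_labels <- c(bag_labels, .parse_label(as.character(bag$label), where))
    for (inst in bag$instances) {
      v <- .parse_bits(as.character(inst$bits), n_bits, where)
      n_bits <- length(v)
      bits[[length(bits) + 1L]] <- v
      bag_of_row <- c(bag_of_row, b)
      instance_ids <- c(instance_ids,
                        as.character(inst$id %||% paste0("inst", length(bits))))
    }
  }
  if (anyDuplicated(bag_ids)) stop("duplicate bag id in ", path)
  if (anyDuplicated(instance_ids)) stop("duplicate instance id in ", path)
  mil_dataset(do.call(rbind, bits), bag_of_row, bag_labels,
              bag_ids, instance_ids)
}

#' Write a multiple-instance dataset to TSV or JSON
#'
#' Inverse of \code{\link{read_mil}}: files written here read back to an
#' identical dataset, bit-exact.
#'
#' @param d a \code{mil_dataset}.
#' @param path file to write.
#' @param format \code{"tsv"} or \code{"json"}; default from extension.
#' @export
write_mil <- function(d, path, format = c("auto", "tsv", "json")) {
  stopifnot(inherits(d, "mil_dataset"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  strings <- apply(d$instances, 1L, paste, collapse = "")
  if (format == "tsv") {
    lines <- c("bag_id\tbag_label\tinstance_id\tbitstring",
               sprintf("%s\t%+d\t%s\t%s",
                       d$bag_ids[d$bag_of_row], as.integer(d$bag_labels[d$bag_of_row]),
                       d$instance_ids, strings))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    rows <- bag_row_list(d)
    bags <- lapply(seq_along(rows), function(b) {
      list(id = d$bag_ids[b], label = as.integer(d$bag_labels[b]),
           instances = lapply(rows[[b]], function(r)
             list(id = d$instance_ids[r], bits = strings[r])))
    })
    jsonlite::write_json(list(n_bits = ncol(d$instances), bags = bags),
                         path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(NULL)
}
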