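# Source vectors: labeled set partitions of the k putative replicates,
# encoded as restricted-growth strings (element d <= 1 + max of elements 1..d-1,
# first element always 1). Equal labels mean "same underlying genotype source".

#' Enumerate all source vectors for k putative replicates
#'
#' A source vector assigns each of the `k` putative replicates of one
#' individual to a genotype source: equal entries mean the samples derive
#' from an identical genotype. Vectors are canonical restricted-growth
#' strings, so each labeled partition of the `k` samples appears exactly
#' once; the number of vectors is the k-th Bell number (1, 2, 5, 15, 52,
#' 203, 877, 4140 for k = 1..8).
#'
#' @param k Number of putative replicates; a single integer in 1..8. The
#'   partition count grows super-exponentially, and joint analysis beyond
#'   k = 7 is not recommended; k > 8 is refused outright.
#' @return A list of integer vectors of length `k`, in lexicographic order,
#'   starting with the all-ones vector (no errors among replicates).
#' @examples
#' enumerate_source_vectors(3) # 5 partitions of 3 samples
#' @export
enumerate_source_vectors <- function(k) {
  k <- assert_count(k, "k")
  if (k > 8L) {
    stop("k = ", k, " exceeds the supported cap of 8 replicates ",
         "(the number of source vectors is the Bell number of k; ",
         "joint analysis beyond k = 7 is not recommended)", call. = FALSE)
  }
  vecs <- list(1L)
  if (k > 1L) {
    for (d in 2L:k) {
      vecs <- unlist(lapply(vecs, function(v) {
        lapply(seq_len(max(v) + 1L), function(lab) c(v, lab))
      }), recursive = FALSE)
    }
  }
  vecs
}

#' Canonicalize a partition labeling into restricted-growth form
#'
#' Relabels an arbitrary positive-integer partition labeling so that labels
#' appear in order of first occurrence (the first element becomes 1). Two
#' labelings describe the same partition iff they canonicalize identically.
#'
#' @param labels Integer vector of group labels, one per sample.
#' @return An integer vector in restricted-growth form.
#' @examples
#' canonicalize_source_vector(c(2, 7, 2)) # (1, 2, 1)
#' @export
canonicalize_source_vector <- function(labels) {
  if (length(labels) < 1L || anyNA(labels)) {
    stop("`labels` must be a non-empty vector of group labels", call. = FALSE)
  }
  match(labels, unique(labels))
}

validate_source_vector <- function(S, k = NULL) {
  if (!is.numeric(S) || length(S) < 1L || anyNA(S) || any(S != as.integer(S))) {
    stop("a source vector must be a non-empty integer vector", call. = FALSE)
  }
  S <- as.integer(S)
  if (!is.null(k) && length(S) != k) {
    stop("source vector has length ", length(S), " but k = ", k, call. = FALSE)
  }
  running_max <- cummax(c(0L, S[-length(S)]))
  if (S[1L] != 1L || any(S > running_max + 1L) || any(S < 1L)) {
    stop("source vector (", paste(S, collapse = ","),
         ") is not in canonical restricted-growth form; ",
         "use canonicalize_source_vector()", call. = FALSE)
  }
  S
}

#' Render a source vector as comma-joined labels
#'
#' @param S Integer source vector.
#' @return A string such as `"1,2,1"`, the form used in all reports and
#'   command-line I/O.
#' @export
format_source_vector <- function(S) paste(S, collapse = ",")

#' Parse a comma-joined source vector string
#'
#' @param x A string such as `"1,2,1"`.
#' @return An integer source vector (validated restricted-growth form).
#' @export
parse_source_vector <- function(x) {
  S <- suppressWarnings(as.integer(strsplit(x, ",", fixed = TRUE)[[1L]]))
  if (length(S) == 0L || anyNA(S)) {
    stop("cannot parse source vector from '", x, "'", call. = FALSE)
  }
  validate_source_vector(S)
}

#' Representative source vectors, one per partition shape
#'
#' Simulation accuracy is a function of the partition shape (the multiset of
#' group sizes), not the labeling: evaluating (1,1,2) is equivalent to
#' evaluating (1,2,1) and (1,2,2). This returns the first enumerated vector
#' of each shape, the canonical representative used by the experiment
#' drivers.
#'
#' @param k Number of replicates (1..8).
#' @return A list of integer source vectors, e.g. `(1,1,1), (1,1,2), (1,2,3)`
#'   for k = 3.
#' @export
source_vector_classes <- function(k) {
  vecs <- enumerate_source_vectors(k)
  shapes <- vapply(vecs, function(v) {
    paste(sort(tabulate(v), decreasing = TRUE), collapse = "+")
  }, character(1))
  vecs[!duplicated(shapes)]
}

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != as.integer(x)) {
    stop("`", name, "` must be a single positive integer", call. = FALSE)
  }
  as.integer(x)
}
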