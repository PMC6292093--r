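# The replicate dataset container: k samples x L sites of allelic depths,
# with per-site population B-allele frequencies.

#' Construct a replicate dataset
#'
#' The container consumed by [joint_posterior()]: allelic depth matrices for
#' the k putative replicates of one individual at L biallelic sites, the
#' per-site population B-allele frequency, and the read error rate. Allele
#' B is bound to the VCF ALT allele throughout the package; the model is
#' symmetric in the two alleles so the convention is harmless as long as it
#' is applied consistently to depths and frequencies.
#'
#' @param sample_ids Character vector of k sample names.
#' @param chrom Character/factor vector of L chromosome identifiers.
#' @param pos Integer vector of L 1-based positions.
#' @param freq_B Numeric vector of L population B-allele frequencies,
#'   each strictly inside (0, 1).
#' @param n_A,n_B Integer L x k matrices of per-site, per-sample read counts
#'   for alleles A (REF) and B (ALT). Zero-depth entries are allowed and
#'   contribute likelihood 1.
#' @param error_rate Per-read sequencing error rate in (0, 0.5).
#' @return An object of class `replicate_dataset`.
#' @export
replicate_dataset <- function(sample_ids, chrom, pos, freq_B, n_A, n_B,
                              error_rate = 0.01) {
  n_A <- as.matrix(n_A)
  n_B <- as.matrix(n_B)
  k <- length(sample_ids)
  L <- length(pos)
  if (L < 1L) stop("a replicate dataset needs at least one site", call. = FALSE)
  if (k < 1L) stop("a replicate dataset needs at least one sample", call. = FALSE)
  if (!all(dim(n_A) == c(L, k)) || !all(dim(n_B) == c(L, k))) {
    stop("`n_A` and `n_B` must be L x k matrices (L = ", L, ", k = ", k, ")",
         call. = FALSE)
  }
  if (length(chrom) != L || length(freq_B) != L) {
    stop("`chrom`, `pos` and `freq_B` must all have length L = ", L, call. = FALSE)
  }
  assert_counts(n_A, "n_A")
  assert_counts(n_B, "n_B")
  assert_freq(freq_B)
  assert_error_rate(error_rate)
  structure(
    list(sample_ids = as.character(sample_ids),
         chrom = as.character(chrom),
         pos = as.integer(pos),
         freq_B = as.numeric(freq_B),
         n_A = matrix(as.integer(n_A), L, k, dimnames = list(NULL, sample_ids)),
         n_B = matrix(as.integer(n_B), L, k, dimnames = list(NULL, sample_ids)),
         error_rate = error_rate),
    class = "replicate_dataset")
}

#' @export
print.replicate_dataset <- function(x, ...) {
  cat("replicate_dataset: ", length(x$sample_ids), " samples x ",
      length(x$pos), " sites\n", sep = "")
  cat("  samples:    ", paste(x$sample_ids, collapse = ", "), "\n", sep = "")
  cat("  error rate: ", x$error_rate, "\n", sep = "")
  cat("  mean depth: ",
      paste(sprintf("%.2f", colMeans(x$n_A + x$n_B)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.replicate_dataset <- function(x) c(length(x$pos), length(x$sample_ids))

#' Write a replicate dataset to the tabular interchange format
#'
#' Tab-separated text with columns `chrom`, `pos`, `freq_B`, then an
#' `<id>.nA` / `<id>.nB` column pair per sample. The error rate is stored
#' in a `#error_rate=` header comment so a round trip is lossless.
#'
#' @param data A `replicate_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "replicate_dataset"))
  df <- data.frame(chrom = data$chrom, pos = data$pos, freq_B = data$freq_B,
                   check.names = FALSE)
  for (i in seq_along(data$sample_ids)) {
    id <- data$sample_ids[i]
    df[[paste0(id, ".nA")]] <- data$n_A[, i]
    df[[paste0(id, ".nB")]] <- data$n_B[, i]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#error_rate=", format(data$error_rate, digits = 17)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a replicate dataset from the tabular interchange format
#'
#' @param path File written by [write_dataset()].
#' @param error_rate Overrides the error rate stored in the file header
#'   (default: use the stored value, or 0.01 if absent).
#' @return A `replicate_dataset`.
#' @export
read_dataset <- function(path, error_rate = NULL) {
  first <- readLines(path, n = 1L)
  stored_e <- if (startsWith(first, "#error_rate=")) {
    as.numeric(sub("^#error_rate=", "", first))
  } else {
    0.01
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE)
  required <- c("chrom", "pos", "freq_B")
  if (!all(required %in% names(df))) {
    stop("interchange file must have columns chrom, pos, freq_B", call. = FALSE)
  }
  nA_cols <- grep("\\.nA$", names(df), value = TRUE)
  ids <- sub("\\.nA$", "", nA_cols)
  nB_cols <- paste0(ids, ".nB")
  if (length(ids) == 0L || !all(nB_cols %in% names(df))) {
    stop("interchange file must have an <id>.nA / <id>.nB column pair per sample",
         call. = FALSE)
  }
  replicate_dataset(
    sample_ids = ids,
    chrom = df$chrom, pos = df$pos, freq_B = df$freq_B,
    n_A = as.matrix(df[nA_cols]), n_B = as.matrix(df[nB_cols]),
    error_rate = if (is.null(error_rate)) stored_e else error_rate)
}
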