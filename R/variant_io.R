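# VCF import of per-sample allelic depths, panel-based allele frequency
# estimation, and seeded site sampling under MAF / distance / coverage
# filters. Parsing is delegated to VariantAnnotation::readVcf; this module
# flattens the AD field into plain integer matrices.

#' Read per-sample allelic depths from a VCF into a site catalog
#'
#' Keeps biallelic SNP records only (multiallelic records, indels and
#' symbolic alleles are skipped and counted). The per-sample `AD` FORMAT
#' field must be present, with the REF count first (`Number=R` convention);
#' missing AD entries (`.`) become `(0, 0)` and thus contribute likelihood
#' 1 downstream.
#'
#' @param vcf_source Path to a VCF file (plain or bgzipped).
#' @param sample_ids Optional character vector restricting the catalog to
#'   these samples; default: all samples in the file.
#' @return An object of class `site_catalog`: a list with `chrom`, `pos`,
#'   `ref`, `alt`, `sample_ids`, integer matrices `n_A` and `n_B` (sites x
#'   samples), `freq_B` (all `NA` until frequencies are attached or
#'   estimated), and `n_skipped` (records dropped by the biallelic-SNP
#'   filter).
#' @export
read_allele_depths <- function(vcf_source, sample_ids = NULL) {
  vcf <- VariantAnnotation::readVcf(vcf_source)
  hdr_fmt <- rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf)))
  if (!"AD" %in% hdr_fmt) {
    stop("VCF has no per-sample 'AD' (allelic depth) FORMAT field; ",
         "the method requires raw allele read counts", call. = FALSE)
  }
  all_ids <- colnames(vcf)
  if (is.null(sample_ids)) {
    sample_ids <- all_ids
  } else {
    missing_ids <- setdiff(sample_ids, all_ids)
    if (length(missing_ids) > 0L) {
      stop("sample(s) not in VCF: ", paste(missing_ids, collapse = ", "),
           "; available: ", paste(all_ids, collapse = ", "), call. = FALSE)
    }
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  alt1 <- rep(NA_character_, length(n_alt))
  alt1[n_alt >= 1L] <- vapply(as.list(alt_list[n_alt >= 1L]),
                              function(a) as.character(a)[1L], character(1))
  keep <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  if (!any(keep)) {
    warning("no usable biallelic SNP records in ", vcf_source,
            " (", n_skipped, " record(s) skipped)", call. = FALSE)
  }
  ad <- VariantAnnotation::geno(vcf)$AD
  col_idx <- match(sample_ids, all_ids)
  L_all <- length(ref)
  n_A <- matrix(0L, L_all, length(sample_ids))
  n_B <- matrix(0L, L_all, length(sample_ids))
  if (is.list(ad)) {
    # ragged AD (mixed allele counts): one integer vector per cell
    for (j in seq_along(col_idx)) {
      cells <- ad[, col_idx[j]]
      a <- vapply(cells, function(x) {
        if (length(x) < 1L || is.na(x[1L])) 0L else as.integer(x[1L])
      }, integer(1))
      b <- vapply(cells, function(x) {
        if (length(x) < 2L || is.na(x[2L])) 0L else as.integer(x[2L])
      }, integer(1))
      n_A[, j] <- a
      n_B[, j] <- b
    }
  } else if (length(dim(ad)) == 3L) {
    a <- ad[, col_idx, 1L, drop = FALSE]
    b <- ad[, col_idx, 2L, drop = FALSE]
    a[is.na(a)] <- 0L
    b[is.na(b)] <- 0L
    n_A[] <- a
    n_B[] <- b
  } else {
    stop("unrecognized AD layout in VCF", call. = FALSE)
  }
  structure(
    list(chrom = as.character(GenomicRanges::seqnames(rr))[keep],
         pos = GenomicRanges::start(rr)[keep],
         ref = ref[keep],
         alt = alt1[keep],
         sample_ids = sample_ids,
         n_A = n_A[keep, , drop = FALSE],
         n_B = n_B[keep, , drop = FALSE],
         freq_B = rep(NA_real_, sum(keep)),
         n_skipped = n_skipped),
    class = "site_catalog")
}

#' @export
print.site_catalog <- function(x, ...) {
  cat("site_catalog: ", length(x$pos), " biallelic SNP sites x ",
      length(x$sample_ids), " samples (", x$n_skipped, " records skipped)\n",
      sep = "")
  cat("  frequencies attached at ", sum(!is.na(x$freq_B)), " sites\n", sep = "")
  invisible(x)
}

match_samples <- function(catalog, ids, what) {
  idx <- match(ids, catalog$sample_ids)
  if (length(ids) == 0L) stop("`", what, "` must name at least one sample",
                              call. = FALSE)
  if (anyNA(idx)) {
    stop(what, " not in catalog: ", paste(ids[is.na(idx)], collapse = ", "),
         "; available: ", paste(catalog$sample_ids, collapse = ", "),
         call. = FALSE)
  }
  idx
}

#' Estimate population B-allele frequencies from a reference panel
#'
#' Pools read counts across the panel samples at each site:
#' `freq_B = sum(n_B) / sum(n_A + n_B)`. This depth-weighted estimator
#' needs no genotype calls, which is the point of the whole approach at
#' shallow depth. Sites with zero panel reads get `NA` and are excluded
#' from site sampling; sites where every panel read carries one allele get
#' frequency 0 or 1 and are later rejected as monomorphic.
#'
#' @param catalog A `site_catalog`.
#' @param panel_sample_ids Samples to pool; must be present in the catalog.
#' @return The catalog with its `freq_B` field filled in.
#' @export
estimate_allele_frequencies <- function(catalog, panel_sample_ids) {
  stopifnot(inherits(catalog, "site_catalog"))
  idx <- match_samples(catalog, panel_sample_ids, "panel_sample_ids")
  b <- rowSums(catalog$n_B[, idx, drop = FALSE])
  total <- rowSums(catalog$n_A[, idx, drop = FALSE]) + b
  freq <- ifelse(total > 0, b / total, NA_real_)
  catalog$freq_B <- freq
  catalog
}

#' Read a per-site allele frequency table
#'
#' Tab-separated file with a header and columns `chrom`, `pos` (1-based)
#' and `freq_B` (ALT-allele frequency).
#'
#' @param path Path to the TSV file.
#' @return Data frame with those three columns.
#' @export
read_frequency_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  required <- c("chrom", "pos", "freq_B")
  if (!all(required %in% names(df))) {
    stop("frequency table must have header columns chrom, pos, freq_B",
         call. = FALSE)
  }
  df$chrom <- as.character(df$chrom)
  df[required]
}

#' Attach externally supplied allele frequencies to a catalog
#'
#' @param catalog A `site_catalog`.
#' @param freq_table Data frame as returned by [read_frequency_table()].
#' @return The catalog with `freq_B` set where the table has a matching
#'   `(chrom, pos)`; unmatched sites keep `NA` and are excluded from
#'   sampling.
#' @export
attach_frequencies <- function(catalog, freq_table) {
  stopifnot(inherits(catalog, "site_catalog"))
  key_cat <- paste(catalog$chrom, catalog$pos)
  key_tab <- paste(as.character(freq_table$chrom), freq_table$pos)
  idx <- match(key_cat, key_tab)
  catalog$freq_B <- ifelse(is.na(idx), NA_real_, freq_table$freq_B[idx])
  catalog
}

#' Site sampling configuration
#'
#' @param L Target number of analysis sites (default 1000).
#' @param maf_min,maf_max Half-open minor-allele-frequency window
#'   `(maf_min, maf_max]`; defaults `(0.4, 0.5]`, the most informative
#'   window for distinguishing genotype sources.
#' @param min_distance Minimum distance in base pairs between any two
#'   sampled sites on the same chromosome (default 20000), a cheap guard
#'   against linkage disequilibrium violating the site-independence
#'   assumption.
#' @param seed Integer seed making the sampled site set reproducible.
#' @param require_read_each If `TRUE` (default), only sites where every
#'   analyzed replicate has at least one read are eligible.
#' @return An object of class `sampling_config`.
#' @export
sampling_config <- function(L = 1000, maf_min = 0.4, maf_max = 0.5,
                            min_distance = 20000, seed = 1L,
                            require_read_each = TRUE) {
  L <- assert_count(L, "L")
  if (!is.numeric(maf_min) || !is.numeric(maf_max) ||
      maf_min < 0 || maf_min >= maf_max || maf_max > 0.5) {
    stop("need 0 <= maf_min < maf_max <= 0.5", call. = FALSE)
  }
  if (min_distance < 0) stop("`min_distance` must be >= 0", call. = FALSE)
  structure(list(L = L, maf_min = maf_min, maf_max = maf_max,
                 min_distance = min_distance, seed = as.integer(seed),
                 require_read_each = isTRUE(require_read_each)),
            class = "sampling_config")
}

#' Sample analysis sites and assemble a replicate dataset
#'
#' Eligible sites have an attached, polymorphic frequency (`freq_B`
#' strictly inside (0,1)) with `MAF = min(freq_B, 1 - freq_B)` in the
#' window `(maf_min, maf_max]`, and — when `require_read_each` — at least
#' one read in every analyzed replicate. Candidates are visited in a
#' seeded random order and accepted greedily if they lie at least
#' `min_distance` bp from every previously accepted site on the same
#' chromosome, until `L` sites are accepted. If fewer than `L` qualify,
#' all qualifying sites are returned with a warning.
#'
#' @param catalog A `site_catalog` with frequencies attached.
#' @param config A [sampling_config()].
#' @param replicate_ids The putative replicate samples to analyze.
#' @param error_rate Error rate stored in the resulting dataset.
#' @return A [replicate_dataset()] with sites in genomic order.
#' @export
sample_sites <- function(catalog, config, replicate_ids, error_rate = 0.01) {
  stopifnot(inherits(catalog, "site_catalog"),
            inherits(config, "sampling_config"))
  idx <- match_samples(catalog, replicate_ids, "replicate_ids")
  if (all(is.na(catalog$freq_B))) {
    stop("catalog has no allele frequencies; run estimate_allele_frequencies() ",
         "or attach_frequencies() first", call. = FALSE)
  }
  f <- catalog$freq_B
  maf <- pmin(f, 1 - f)
  eligible <- !is.na(f) & f > 0 & f < 1 &
    maf > config$maf_min & maf <= config$maf_max
  if (config$require_read_each) {
    depth <- catalog$n_A[, idx, drop = FALSE] + catalog$n_B[, idx, drop = FALSE]
    eligible <- eligible & rowSums(depth >= 1L) == length(idx)
  }
  candidates <- which(eligible)
  if (length(candidates) == 0L) {
    stop("no sites pass the filters (MAF window (", config$maf_min, ",",
         config$maf_max, "], coverage in every replicate); ",
         "widen the MAF window or relax require_read_each", call. = FALSE)
  }
  # sample.int guards against sample()'s length-1 expansion
  visit <- withr::with_seed(config$seed,
                            candidates[sample.int(length(candidates))])
  accepted <- integer(0)
  for (v in visit) {
    same_chr <- accepted[catalog$chrom[accepted] == catalog$chrom[v]]
    if (length(same_chr) == 0L ||
        all(abs(catalog$pos[same_chr] - catalog$pos[v]) >= config$min_distance)) {
      accepted <- c(accepted, v)
      if (length(accepted) == config$L) break
    }
  }
  if (length(accepted) < config$L) {
    warning("only ", length(accepted), " of the requested ", config$L,
            " sites satisfy the MAF/distance/coverage filters; returning all",
            call. = FALSE)
  }
  accepted <- accepted[order(catalog$chrom[accepted], catalog$pos[accepted])]
  replicate_dataset(
    sample_ids = replicate_ids,
    chrom = catalog$chrom[accepted],
    pos = catalog$pos[accepted],
    freq_B = catalog$freq_B[accepted],
    n_A = catalog$n_A[accepted, idx, drop = FALSE],
    n_B = catalog$n_B[accepted, idx, drop = FALSE],
    error_rate = error_rate)
}
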