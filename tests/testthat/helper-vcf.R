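# Writes small VCF fixtures as plain text at test time.
#
# `ad` is an L x n character matrix of AD strings ("3,1", ".", "1,2,0" for
# multiallelic records); alt may contain comma-joined alleles or indels to
# exercise the biallelic-SNP filter.
write_test_vcf <- function(path, chrom, pos, ref, alt, ad, sample_ids,
                           format_field = "AD") {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
  body <- vapply(seq_along(pos), function(i) {
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", "PASS", ".",
            format_field, ad[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# Render a simulated replicate_dataset (plus optional extra panel samples)
# as a VCF, so the end-to-end VCF -> posterior path can be tested against
# known truth.
dataset_to_vcf <- function(data, path, extra = NULL) {
  ad <- matrix(paste0(data$n_A, ",", data$n_B),
               nrow = length(data$pos))
  ids <- data$sample_ids
  if (!is.null(extra)) {
    ad <- cbind(ad, matrix(paste0(extra$n_A, ",", extra$n_B),
                           nrow = length(data$pos)))
    ids <- c(ids, extra$sample_ids)
  }
  write_test_vcf(path,
                 chrom = data$chrom, pos = data$pos,
                 ref = rep("A", length(data$pos)),
                 alt = rep("C", length(data$pos)),
                 ad = ad, sample_ids = ids)
}

write_freq_table <- function(path, chrom, pos, freq_B) {
  utils::write.table(data.frame(chrom = chrom, pos = pos, freq_B = freq_B),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
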