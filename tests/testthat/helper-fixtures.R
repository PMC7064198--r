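# Programmatic fixtures (no stored data files beyond the tiny example VCF).

# Minimal single-sample-block VCF with given genotype strings per site.
write_fixture_vcf <- function(path, gt, ids = NULL, sample_names = NULL) {
  # gt: list of character vectors (one per site, one entry per sample)
  n <- length(gt[[1]])
  if (is.null(sample_names)) sample_names <- paste0("s", seq_len(n))
  if (is.null(ids)) ids <- paste0("rs", seq_along(gt))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  body <- vapply(seq_along(gt), function(r) {
    paste(c("1", as.character(1000 + r), ids[r], "A",
            if (any(grepl("2", gt[[r]]))) "C,G" else "C",
            ".", "PASS", ".", "GT", gt[[r]]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# A small deterministic genotype panel with well-separated rare/common MAFs.
fixture_panel <- function() c(r1 = 0.01, r2 = 0.02, r3 = 0.03, r4 = 0.04,
                              c1 = 0.2, c2 = 0.4)
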